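## End-to-end orchestration: simulate (or load) -> validate sites ->
## linkage per condition -> intersect -> DEG contrasts -> integrate.
## Everything is seeded from one integer and all outputs are plain TSV /
## GFF3 / JSON, so identical config + seed gives byte-identical artifacts.

.logmsg <- function(cfg, ...) {
  if (cfg@log_level != "quiet")
    message("[bsrseq] ", ...)
}

#' Run the full BSR-seq analysis pipeline
#'
#' With `simulate = TRUE` (default) a synthetic dataset is generated from
#' `cfg@simulation` (seeded by `cfg@seed`) and written to `cfg@outdir`;
#' otherwise `inputs` must name existing files.  The stages then run in
#' order: site validation, per-condition linkage scan, high-probability
#' calls and their cross-condition intersection, SNP-to-gene assignment,
#' the four DEG contrasts (within-bulk waterlogged vs normal; between-bulk
#' per condition), the between-bulk contrast overlap, and the candidate
#' table.  A JSON manifest records the package version, seed, every
#' parameter, and the md5 digest of every file written.
#'
#' @param cfg a [pipelineConfig()].
#' @param simulate generate inputs from `cfg@simulation`?
#' @param inputs when `simulate = FALSE`: list with `counts` (named
#'   character vector of per-condition allele-count TSVs), `matrix`
#'   (count-matrix TSV) and `genes` (GFF3).
#' @param region optional marker interval passed to [integrateSnpDeg()].
#' @return invisibly, a list with the in-memory stage results
#'   (`filtered`, `linkage`, `calls`, `overlap_snps`, `snp_genes`,
#'   `chromosome_counts`, `degs`, `deg_overlap`, `candidates`,
#'   `manifest`).
#' @export
runPipeline <- function(cfg = pipelineConfig(), simulate = TRUE,
                        inputs = NULL, region = NULL) {
  dir.create(cfg@outdir, showWarnings = FALSE, recursive = TRUE)
  simCfg <- cfg@simulation
  simCfg@seed <- cfg@seed
  manifest <- list(package = "bsrseq",
                   version = as.character(utils::packageVersion("bsrseq")),
                   seed = cfg@seed,
                   parameters = .configAsList(cfg))
  if (simulate) {
    .logmsg(cfg, "simulating panel (seed ", cfg@seed, ")")
    truth <- simulatePanel(simCfg)
    genes <- simulateGeneModels(simCfg, seed = cfg@seed + 1L)
    expr <- simulateExpression(simCfg, geneLength = width(genes),
                               seed = cfg@seed + 2L)
    actNormal <- simulateAlleleCounts(truth, simCfg, "normal",
                                      seed = cfg@seed + 3L)
    actWater <- simulateAlleleCounts(truth, simCfg, "waterlogged",
                                     seed = cfg@seed + 4L)
    act <- combineAlleleCounts(actNormal, actWater)
    simFiles <- writeSimulation(cfg@outdir, truth,
                                list(normal = actNormal,
                                     waterlogged = actWater),
                                expr, genes)
    em <- expr$matrix
  } else {
    if (is.null(inputs))
      stop("stage 'input': no input files given and simulation disabled")
    for (f in c(inputs$counts, inputs$matrix, inputs$genes))
      if (!file.exists(f))
        stop("stage 'input': missing file ", f)
    tabs <- lapply(inputs$counts, readAlleleCounts)
    act <- if (length(tabs) > 1L) do.call(combineAlleleCounts, unname(tabs))
           else tabs[[1L]]
    em <- readCountMatrix(inputs$matrix)
    genes <- readGeneModels(inputs$genes)
    truth <- NULL
    simFiles <- character(0)
  }

  .logmsg(cfg, "validating ", length(act), " SNP sites")
  filt <- filterSites(act, cfg@snp_filter)
  .logmsg(cfg, sum(filt$summary["pass"]), " sites pass the two-type rules")

  conds <- conditionNames(filt$table)
  linkage <- lapply(conds, function(cc)
    scanLinkage(filt$table, cc, cfg@linkage))
  names(linkage) <- conds
  calls <- lapply(linkage, callHighProbability,
                  threshold = cfg@linkage@call_threshold)
  for (cc in conds) {
    .logmsg(cfg, length(calls[[cc]]), " high-probability SNPs under ", cc)
    .writeLinkageTsv(linkage[[cc]],
                     file.path(cfg@outdir,
                               sprintf("linkage_%s.tsv", cc)))
  }
  if (length(conds) >= 2L) {
    ov <- intersectHighProbability(calls[[1L]], calls[[2L]])
  } else {
    ov <- list(overlap = calls[[1L]], n_only_a = 0L, n_only_b = 0L)
  }
  .logmsg(cfg, length(ov$overlap), " SNPs overlap across conditions")
  snpGenes <- assignSnpsToGenes(ov$overlap, genes)
  chromCounts <- lapply(calls, summarizeByChromosome,
                        chromosomes = names(simCfg@chromosomes))

  samples <- colnames(em)
  grp <- function(bulk, cond) samples[grepl(paste0("^", bulk, "_", cond), samples)]
  contrasts <- list(
    tolerant_wl_vs_normal   = list(a = grp("tolerant", "waterlogged"),
                                   b = grp("tolerant", "normal")),
    sensitive_wl_vs_normal  = list(a = grp("sensitive", "waterlogged"),
                                   b = grp("sensitive", "normal")),
    t_vs_s_normal           = list(a = grp("tolerant", "normal"),
                                   b = grp("sensitive", "normal")),
    t_vs_s_waterlogged      = list(a = grp("tolerant", "waterlogged"),
                                   b = grp("sensitive", "waterlogged")))
  contrasts <- Filter(function(x) length(x$a) && length(x$b), contrasts)
  degs <- lapply(contrasts, function(ct) callDegs(em, ct$a, ct$b, cfg@deg))
  for (nm in names(degs)) {
    .logmsg(cfg, sum(degs[[nm]]$significant), " DEGs in contrast ", nm)
    .writeDegTsv(degs[[nm]],
                 file.path(cfg@outdir, sprintf("deg_%s.tsv", nm)))
  }
  degOverlap <- NULL
  if (all(c("t_vs_s_normal", "t_vs_s_waterlogged") %in% names(degs)))
    degOverlap <- overlapDegSets(degs$t_vs_s_normal, degs$t_vs_s_waterlogged)

  candidates <- integrateSnpDeg(ov$overlap, genes, degs, region = region)
  utils::write.table(candidates,
                     file.path(cfg@outdir, "candidate_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  outFiles <- list.files(cfg@outdir, full.names = TRUE)
  outFiles <- outFiles[!grepl("manifest[.]json$", outFiles)]
  manifest$files <- as.list(tools::md5sum(sort(outFiles)))
  manifest$summaries <- list(
    filter = as.list(filt$summary),
    high_prob = lapply(calls, length),
    overlap = length(ov$overlap),
    degs = lapply(degs, function(d) sum(d$significant)),
    deg_overlap = if (!is.null(degOverlap)) degOverlap$class_counts else NULL,
    candidates = nrow(candidates))
  jsonlite::write_json(manifest, file.path(cfg@outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(truth = truth, table = act, filtered = filt,
                 linkage = linkage, calls = calls, overlap_snps = ov,
                 snp_genes = snpGenes, chromosome_counts = chromCounts,
                 expression = em, degs = degs, deg_overlap = degOverlap,
                 candidates = candidates, manifest = manifest))
}

.writeLinkageTsv <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                   as.data.frame(mcols(gr)), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.writeDegTsv <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## every numeric knob of every stage, flattened for the manifest
.configAsList <- function(cfg) {
  one <- function(obj) {
    s <- methods::slotNames(class(obj))
    vals <- lapply(s, function(nm) {
      v <- methods::slot(obj, nm)
      if (is.numeric(v) || is.character(v) || is.logical(v)) v else NULL
    })
    names(vals) <- s
    vals[!vapply(vals, is.null, logical(1))]
  }
  list(read_qc = one(cfg@read_qc), snp_filter = one(cfg@snp_filter),
       linkage = one(cfg@linkage), deg = one(cfg@deg),
       simulation = one(cfg@simulation),
       seed = cfg@seed, log_level = cfg@log_level)
}
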