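contrast	direction	bin	n
tolerant_wl_vs_normal	up	>1000	2
tolerant_wl_vs_normal	up	100-1000	6
tolerant_wl_vs_normal	up	10-100	37
tolerant_wl_vs_normal	up	2-10	136
tolerant_wl_vs_normal	down	>1000	1
tolerant_wl_vs_normal	down	100-1000	2
tolerant_wl_vs_normal	down	10-100	16
tolerant_wl_vs_normal	down	2-10	154
sensitive_wl_vs_normal	up	>1000	3
sensitive_wl_vs_normal	up	100-1000	26
sensitive_wl_vs_normal	up	10-100	126
sensitive_wl_vs_normal	up	2-10	400
sensitive_wl_vs_normal	down	>1000	2
sensitive_wl_vs_normal	down	100-1000	12
sensitive_wl_vs_normal	down	10-100	79
sensitive_wl_vs_normal	down	2-10	446
t_vs_s_normal	up	>1000	3
t_vs_s_normal	up	100-1000	19
t_vs_s_normal	up	10-100	49
t_vs_s_normal	up	2-10	327
t_vs_s_normal	down	>1000	4
t_vs_s_normal	down	100-1000	18
t_vs_s_normal	down	10-100	25
t_vs_s_normal	down	2-10	148
t_vs_s_waterlogged	up	>1000	5
t_vs_s_waterlogged	up	100-1000	23
t_vs_s_waterlogged	up	10-100	39
t_vs_s_waterlogged	up	2-10	112
t_vs_s_waterlogged	down	>1000	2
t_vs_s_waterlogged	down	100-1000	29
t_vs_s_waterlogged	down	10-100	48
t_vs_s_waterlogged	down	2-10	173
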