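# Published microarray-only (baseline) sensitivity/specificity for the two
# cancers where they were reported, plus the combined-method values they are
# compared against. The pancreatic baseline specificity is quoted once as
# 0.435 and used as 0.437 in the published increase-rate arithmetic; both are
# kept. increase-rate arithmetic uses the *_arith columns.
disease	metric	baseline	baseline_arith	combined	increase_rate_printed
Colon	sensitivity	0.405	0.405	0.476	17.28
Colon	specificity	0.347	0.347	0.429	23.63
Pancreatic	sensitivity	0.519	0.519	0.586	12.9
Pancreatic	specificity	0.435	0.437	0.64	46.45
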