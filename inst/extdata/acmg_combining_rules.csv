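# ACMG/AMP evidence-combination matrix for sequence variants.
# One row per combining rule; counts refer to evidence items at the
# effective strength after per-code overrides:
#   vs = very strong (pathogenic), s = strong (pathogenic),
#   m = moderate, p = supporting (pathogenic),
#   ba = stand-alone (benign), bs = strong (benign), bp = supporting (benign).
# *_min / *_max bound the counts; empty = unconstrained. Rules are
# evaluated top-down within each arm (pathogenic before likely_pathogenic,
# benign before likely_benign); both arms satisfied -> uncertain_significance.
# The table is editable so refined combining recommendations can be swapped in.
rule_id,verdict,vs_min,vs_max,s_min,s_max,m_min,m_max,p_min,p_max,ba_min,bs_min,bs_max,bp_min
P_2VS,pathogenic,2,,,,,,,,,,,
P_Ia,pathogenic,1,,1,,,,,,,,,
P_Ib,pathogenic,1,,,,2,,,,,,,
P_Ic,pathogenic,1,,,,1,,1,,,,,
P_Id,pathogenic,1,,,,,,2,,,,,
P_II,pathogenic,,,2,,,,,,,,,
P_IIIa,pathogenic,,,1,,3,,,,,,,
P_IIIb,pathogenic,,,1,,2,,2,,,,,
P_IIIc,pathogenic,,,1,,1,,4,,,,,
LP_i,likely_pathogenic,1,,,,1,,,,,,,
LP_ii,likely_pathogenic,,,1,,1,2,,,,,,
LP_iii,likely_pathogenic,,,1,,,,2,,,,,
LP_iv,likely_pathogenic,,,,,3,,,,,,,
LP_v,likely_pathogenic,,,,,2,,2,,,,,
LP_vi,likely_pathogenic,,,,,1,,4,,,,,
B_I,benign,,,,,,,,,1,,,
B_II,benign,,,,,,,,,,2,,
LB_i,likely_benign,,,,,,,,,,1,,1
LB_ii,likely_benign,,,,,,,,,,,,2
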