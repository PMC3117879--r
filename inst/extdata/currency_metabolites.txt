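# Optional currency-metabolite blacklist for build_enzyme_graph().
# These ubiquitous cofactor/carrier compounds (KEGG compound IDs) take part
# in a large share of reactions; linking enzymes through them connects
# nearly everything, so pathway-topology analyses often exclude them.
# The default blacklist is empty; pass this file explicitly to enable it.
C00001	# H2O
C00002	# ATP
C00003	# NAD+
C00004	# NADH
C00005	# NADPH
C00006	# NADP+
C00008	# ADP
C00009	# orthophosphate
C00010	# CoA
C00011	# CO2
C00013	# diphosphate
C00014	# NH3
C00020	# AMP
C00080	# H+
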