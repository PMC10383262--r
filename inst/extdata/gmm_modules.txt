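# Curated subset of Gut Metabolic Module definitions (synthetic stand-in
# for the full 103-module catalog; supply your own file for the complete
# set). One step per line (alternative KOs separated by spaces), "//"
# separates alternative reaction paths, "///" ends a module.

MODULE mucin_degradation mucin degradation
K01186
K01206 K15923
K01190 K12309
K01207
K01443
///

MODULE tyrosine_degradation tyrosine degradation
K00815
K00457
K00451
K01800
K01555
///

MODULE pentose_phosphate_oxidative pentose phosphate pathway (oxidative phase)
K00036
K01057 K07404
K00033
///

MODULE cysteine_homocysteine cysteine biosynthesis / homocysteine degradation
K00640
K01738 K10150
K01697
K01758
///

MODULE starch_degradation starch degradation
K01176 K07405
K01200
K01187
///

MODULE galactose_degradation lactose and galactose degradation
K01190 K12308
K00849
K00965
K01784
//
K01220
K00917
K01635
///
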