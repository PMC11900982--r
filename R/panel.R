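# Built-in synthetic metabolite panel.
#
# Formulas are real; m/z values approximate negative-mode [M-H]-
# monoisotopic masses closely enough to exercise envelope extraction.
# Pool sizes and MIDs attached by the scenarios are synthetic.

#' Synthetic metabolite panel
#'
#' A curated panel of central-carbon, nucleoside and redox metabolites
#' used by the co-culture scenario generators. Carbon counts are derived
#' from the formula with [carbon_count()].
#'
#' @param metabolites optional character vector to subset the panel.
#' @return data.frame with `metabolite`, `code`, `formula`, `n_carbons`,
#'   `mz`, `rt`.
#' @export
metabolite_panel <- function(metabolites = NULL) {
  p <- data.frame(
    metabolite = c("glucose", "lactate", "pyruvate", "serine", "glycine",
                   "glutamate", "glutamine", "malate", "citrate",
                   "succinate", "alpha-ketoglutarate", "aspartate",
                   "glutathione", "UDP-GlcNAc", "inosine", "uridine",
                   "hypoxanthine", "uric acid", "orotic acid", "ATP",
                   "ADP", "AMP", "NAD+", "NADH", "acetyl-CoA",
                   "propionyl-CoA", "S-adenosylhomocysteine",
                   "glutamyl-glycine", "uracil", "UMP",
                   "carbamoyl aspartate"),
    code = c("Glc", "L", "Pyr", "S", "G", "E", "Q", "M", "C", "Sc",
             "aKG", "D", "GSH", "U", "Ino", "Urd", "Hpx", "UA", "Oro",
             "ATP", "ADP", "AMP", "NAD", "NADH", "AcCoA", "PrCoA",
             "SAH", "EG", "Ura", "UMP", "CAsp"),
    formula = c("C6H12O6", "C3H6O3", "C3H4O3", "C3H7NO3", "C2H5NO2",
                "C5H9NO4", "C5H10N2O3", "C4H6O5", "C6H8O7", "C4H6O4",
                "C5H6O5", "C4H7NO4", "C10H17N3O6S", "C17H27N3O17P2",
                "C10H12N4O5", "C9H12N2O6", "C5H4N4O", "C5H4N4O3",
                "C5H4N2O4", "C10H16N5O13P3", "C10H15N5O10P2",
                "C10H14N5O7P", "C21H27N7O14P2", "C21H29N7O14P2",
                "C23H38N7O17P3S", "C24H40N7O17P3S", "C14H20N6O5S",
                "C7H12N2O5", "C4H4N2O2", "C9H13N2O9P", "C5H8N2O5"),
    mz = c(179.0561, 89.0244, 87.0088, 104.0353, 74.0247, 146.0459,
           145.0619, 133.0142, 191.0197, 117.0193, 145.0142, 132.0302,
           306.0765, 606.0741, 267.0735, 243.0623, 135.0312, 167.0211,
           155.0098, 505.9885, 426.0221, 346.0558, 662.1018, 664.1175,
           808.1185, 822.1341, 383.1143, 203.0673, 111.0200, 323.0286,
           175.0360),
    rt = round(seq(1.2, 28.4, length.out = 31), 2),
    stringsAsFactors = FALSE)
  p$n_carbons <- carbon_count(p$formula)
  if (!is.null(metabolites)) {
    miss <- setdiff(metabolites, p$metabolite)
    if (length(miss)) stopf("panel lacks metabolites: %s",
                            paste(miss, collapse = ", "))
    p <- p[match(metabolites, p$metabolite), ]
    rownames(p) <- NULL
  }
  p
}
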