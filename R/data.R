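#' Published mutation spectrum of the DuWTill durum TILLING population
#'
#' The per-type mutation counts reported for the 81-line durum wheat EMS
#' TILLING population behind the DuWTill database, called at a minimum
#' mutant-allele coverage of 10 reads: 16 categories (12 substitution types
#' and 4 single-base deletions) totalling 83,573 mutations, of which 49,652
#' were predicted heterozygous and 33,921 homozygous. Useful as a reference
#' input for spectrum summaries and as a realism check for simulations.
#'
#' @return a list with `type_counts` (data.frame `mutation_kind`,
#'   `control_base`, `mutant_allele`, `n`), `n_het` and `n_hom`.
#' @export
duwtill_spectrum <- function() {
  type_counts <- data.frame(
    mutation_kind = c(rep("deletion", 4L), rep("substitution", 12L)),
    control_base = c("A", "C", "G", "T",
                     "A", "A", "A", "C", "C", "C",
                     "G", "G", "G", "T", "T", "T"),
    mutant_allele = c("DEL", "DEL", "DEL", "DEL",
                      "C", "G", "T", "A", "G", "T",
                      "A", "C", "T", "A", "C", "G"),
    n = c(19L, 15L, 23L, 20L,
          53L, 285L, 277L, 1705L, 51L, 39294L,
          39472L, 34L, 1610L, 385L, 240L, 90L),
    stringsAsFactors = FALSE)
  list(type_counts = type_counts, n_het = 49652L, n_hom = 33921L)
}
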