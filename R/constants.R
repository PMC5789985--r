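#' Mutation effect classes
#'
#' The five-class classification used throughout the package. Missense
#' mutations carry a PolyPhen-2-style score in \[0, 1\] and fall into one of
#' three score bands; non-missense coding/splice mutations ("putative null"
#' alleles) are split into class I (nonsense, makesense/stop-loss, start
#' loss) and class II (indels and splice defects) and carry no score.
#'
#' `mutation_classes()` returns the closed set of snake_case class tokens;
#' `class_labels()` returns the corresponding human-readable labels used in
#' printed tables.
#'
#' @return A character vector of class tokens, or a named character vector
#'   mapping token to display label.
#' @export
#' @examples
#' mutation_classes()
#' class_labels()["probably_damaging"]
mutation_classes <- function() {
  c("probably_benign", "possibly_damaging", "probably_damaging",
    "null_class_I", "null_class_II")
}

#' @rdname mutation_classes
#' @export
class_labels <- function() {
  c(probably_benign   = "Probably benign (score <=0.45)",
    possibly_damaging = "Possibly damaging (score 0.45-0.95)",
    probably_damaging = "Probably damaging (score 0.95-1.0)",
    null_class_I      = "Probably null class I",
    null_class_II     = "Probably null class II")
}

#' Classes that carry a prediction score
#' @return Character vector of the three missense class tokens.
#' @export
missense_classes <- function() {
  c("probably_benign", "possibly_damaging", "probably_damaging")
}

#' Default per-class damage probabilities
#'
#' Point estimates of the probability that a mutation of each class causes
#' phenotypically detectable protein damage in the homozygous state,
#' obtained by the method-of-moments estimator on a large ENU mutagenesis
#' cohort restricted to known essential genes. These are the shipped
#' defaults for the saturation calculator and the essentiality simulation;
#' both accept any user-supplied map.
#'
#' @return Named numeric vector over [mutation_classes()].
#' @export
#' @examples
#' default_damage_map()
default_damage_map <- function() {
  c(probably_benign   = 0.045,
    possibly_damaging = 0.099,
    probably_damaging = 0.167,
    null_class_I      = 0.594,
    null_class_II     = 0.626)
}

#' Approximate mouse autosome lengths
#'
#' Lengths in base pairs of mouse chromosomes 1-19 (GRCm38 scale, rounded
#' to the nearest Mb). Used as the default chromosome set by the synthetic
#' pedigree generator so that the 100-Mb isolation filter behaves
#' realistically. Only autosomes are modelled.
#'
#' @return Named integer vector, names "chr1".."chr19".
#' @export
mouse_autosome_lengths <- function() {
  mb <- c(195, 182, 160, 157, 152, 150, 145, 130, 124, 131,
          122, 120, 121, 125, 104, 98, 95, 91, 61)
  stats::setNames(as.integer(mb * 1e6), paste0("chr", seq_along(mb)))
}

GENOTYPE_LEVELS <- c("REF", "HET", "HOM")
GENERATION_LEVELS <- c("G1", "G2", "G3")

# variant-allele transmission probability per parental genotype
TRANSMIT_PROB <- c(REF = 0, HET = 0.5, HOM = 1)
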