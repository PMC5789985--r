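# Readers/writers for the four tabular inputs. All tables are
# tab-delimited UTF-8 with a header row; absent values are ".".
# Every rejected row is reported with its line number (header = line 1);
# nothing is dropped silently.

NA_TOKEN <- "."

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_fmt("%s file not found: %s", what, path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NA_TOKEN,
                          quote = "", comment.char = "", fileEncoding = "UTF-8",
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_fmt("%s file %s is missing required column(s): %s",
             what, path, paste(missing, collapse = ", "))
  df
}

# data line i of a header TSV sits on physical line i + 1
line_no <- function(i) i + 1L

check_closed_set <- function(values, allowed, column, what) {
  bad <- !is.na(values) & !(values %in% allowed)
  if (any(bad)) {
    stop_fmt("%s: invalid %s %s at line(s) %s; permitted values: %s",
             what, column,
             paste(unique(sQuote(values[bad])), collapse = ", "),
             paste(line_no(which(bad)), collapse = ", "),
             paste(allowed, collapse = ", "))
  }
  invisible(NULL)
}

parse_num <- function(values, column, what, lines = seq_along(values)) {
  out <- suppressWarnings(as.numeric(values))
  bad <- !is.na(values) & is.na(out)
  if (any(bad))
    stop_fmt("%s: non-numeric %s at line(s) %s",
             what, column, paste(line_no(lines[bad]), collapse = ", "))
  out
}

#' Read a mutation annotation table
#'
#' Reads the tab-delimited mutation table: one row per validated
#' coding/splicing mutation, with its pedigree of origin, gene, genomic
#' coordinate (1-based bp), effect class and, for missense classes, a
#' prediction score in \[0, 1\]. Null-class mutations must have score "."
#' (absent).
#'
#' @param path Path to a TSV file with columns `mutation_id`,
#'   `pedigree_id`, `gene_id`, `chromosome`, `position`, `mutation_class`,
#'   `score`.
#' @return A data frame of class `mutation_table`, one row per mutation,
#'   with `position` integer and `score` numeric (`NA` for null classes).
#' @seealso [read_genotypes()], [mutation_classes()]
#' @export
read_mutations <- function(path) {
  req <- c("mutation_id", "pedigree_id", "gene_id", "chromosome",
           "position", "mutation_class", "score")
  df <- read_tsv_checked(path, req, "mutations")
  validate_mutations(df[req], where = path)
}

#' @rdname read_mutations
#' @param df A data frame with the same columns as the file contract;
#'   `validate_mutations` checks invariants and returns the typed table.
#' @param where Label used in error messages.
#' @export
validate_mutations <- function(df, where = "mutations") {
  what <- sprintf("mutations (%s)", where)
  check_closed_set(df$mutation_class, mutation_classes(),
                   "mutation_class", what)
  if (anyNA(df$mutation_class))
    stop_fmt("%s: missing mutation_class at line(s) %s", what,
             paste(line_no(which(is.na(df$mutation_class))), collapse = ", "))
  pos <- parse_num(as.character(df$position), "position", what)
  if (anyNA(pos))
    stop_fmt("%s: missing position at line(s) %s", what,
             paste(line_no(which(is.na(pos))), collapse = ", "))
  if (any(pos < 1 | pos != floor(pos) | pos > .Machine$integer.max))
    stop_fmt("%s: position must be a positive 1-based integer (< 2^31); offending line(s) %s",
             what,
             paste(line_no(which(pos < 1 | pos != floor(pos) |
                                   pos > .Machine$integer.max)), collapse = ", "))
  score <- parse_num(as.character(df$score), "score", what)
  is_missense <- df$mutation_class %in% missense_classes()
  if (any(is_missense & is.na(score)))
    stop_fmt("%s: missense mutations require a score; missing at line(s) %s",
             what, paste(line_no(which(is_missense & is.na(score))), collapse = ", "))
  if (any(!is_missense & !is.na(score)))
    stop_fmt("%s: null-class mutations must not carry a score; line(s) %s",
             what, paste(line_no(which(!is_missense & !is.na(score))), collapse = ", "))
  if (any(!is.na(score) & (score < 0 | score > 1)))
    stop_fmt("%s: score outside [0,1] at line(s) %s", what,
             paste(line_no(which(!is.na(score) & (score < 0 | score > 1))), collapse = ", "))
  if (anyDuplicated(df$mutation_id))
    stop_fmt("%s: duplicate mutation_id(s): %s", what,
             paste(unique(df$mutation_id[duplicated(df$mutation_id)]), collapse = ", "))
  out <- data.frame(mutation_id = as.character(df$mutation_id),
                    pedigree_id = as.character(df$pedigree_id),
                    gene_id = as.character(df$gene_id),
                    chromosome = as.character(df$chromosome),
                    position = as.integer(pos),
                    mutation_class = as.character(df$mutation_class),
                    score = score,
                    stringsAsFactors = FALSE)
  class(out) <- c("mutation_table", "data.frame")
  out
}

#' Read a per-mouse genotype table
#'
#' Long-format calls: one row per (mouse, mutation) pair, with pedigree
#' membership, generation (G1/G2/G3), dam and litter for G3 mice, and the
#' genotype call REF / HET / HOM. Each mouse's rows are assembled into its
#' genotype map; duplicate (mouse, mutation) pairs are an error.
#'
#' @param path Path to a TSV with columns `mouse_id`, `pedigree_id`,
#'   `generation`, `dam_id`, `litter_id`, `mutation_id`, `genotype`
#'   (dam_id/litter_id are "." for G1/G2 animals).
#' @return A data frame of class `genotype_table` (one row per call).
#'   Mouse-level attributes are recovered with [mice_of()].
#' @export
read_genotypes <- function(path) {
  req <- c("mouse_id", "pedigree_id", "generation", "dam_id", "litter_id",
           "mutation_id", "genotype")
  df <- read_tsv_checked(path, req, "genotypes")
  validate_genotypes(df[req], where = path)
}

#' @rdname read_genotypes
#' @param df A data frame with the long-format call columns.
#' @param where Label used in error messages.
#' @export
validate_genotypes <- function(df, where = "genotypes") {
  what <- sprintf("genotypes (%s)", where)
  check_closed_set(df$genotype, GENOTYPE_LEVELS, "genotype", what)
  check_closed_set(df$generation, GENERATION_LEVELS, "generation", what)
  if (anyNA(df$genotype) || anyNA(df$generation))
    stop_fmt("%s: missing genotype/generation values", what)
  dup <- duplicated(df[c("mouse_id", "mutation_id")])
  if (any(dup))
    stop_fmt("%s: duplicate (mouse, mutation) record(s) at line(s) %s",
             what, paste(line_no(which(dup)), collapse = ", "))
  g3_no_dam <- df$generation == "G3" & (is.na(df$dam_id) | is.na(df$litter_id))
  if (any(g3_no_dam))
    stop_fmt("%s: G3 mice must have dam_id and litter_id; line(s) %s",
             what, paste(line_no(which(g3_no_dam)), collapse = ", "))
  # one consistent (pedigree, generation, dam, litter) per mouse
  meta <- unique(df[c("mouse_id", "pedigree_id", "generation", "dam_id", "litter_id")])
  if (anyDuplicated(meta$mouse_id))
    stop_fmt("%s: inconsistent pedigree/generation/dam/litter for mouse(s): %s",
             what, paste(unique(meta$mouse_id[duplicated(meta$mouse_id)]), collapse = ", "))
  out <- data.frame(mouse_id = as.character(df$mouse_id),
                    pedigree_id = as.character(df$pedigree_id),
                    generation = as.character(df$generation),
                    dam_id = as.character(df$dam_id),
                    litter_id = as.character(df$litter_id),
                    mutation_id = as.character(df$mutation_id),
                    genotype = as.character(df$genotype),
                    stringsAsFactors = FALSE)
  class(out) <- c("genotype_table", "data.frame")
  out
}

#' One row per mouse from a genotype table
#' @param genotypes A `genotype_table`.
#' @return Data frame with mouse_id, pedigree_id, generation, dam_id,
#'   litter_id.
#' @export
mice_of <- function(genotypes) {
  out <- unique(as.data.frame(genotypes)[
    c("mouse_id", "pedigree_id", "generation", "dam_id", "litter_id")])
  rownames(out) <- NULL
  out
}

#' Read gene essentiality annotations
#'
#' One row per gene with `essential` (TRUE/FALSE) and, for essential
#' genes, the lethality mode (`totally` / `partially`; "." when unknown).
#' A gene annotated both essential and non-essential across rows has
#' conflicting records and is discarded from the output (the number of
#' discarded genes is logged). Consistent duplicates are collapsed.
#'
#' @param path TSV with columns `gene_id`, `essential`, `lethality_mode`.
#' @return Data frame of class `essentiality_table`, one row per retained
#'   gene; attribute `n_conflicting` counts discarded genes.
#' @export
read_essentiality <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "essential", "lethality_mode"),
                         "essentiality")
  what <- sprintf("essentiality (%s)", path)
  check_closed_set(df$essential, c("TRUE", "FALSE", "true", "false"),
                   "essential", what)
  check_closed_set(df$lethality_mode, c("totally", "partially", "unknown"),
                   "lethality_mode", what)
  ess <- toupper(df$essential) == "TRUE"
  if (anyNA(ess))
    stop_fmt("%s: missing essential flag at line(s) %s", what,
             paste(line_no(which(is.na(ess))), collapse = ", "))
  mode <- ifelse(is.na(df$lethality_mode), "unknown", df$lethality_mode)
  if (any(!ess & mode != "unknown"))
    stop_fmt("%s: lethality_mode given for non-essential gene(s) at line(s) %s",
             what, paste(line_no(which(!ess & mode != "unknown")), collapse = ", "))
  tab <- data.frame(gene_id = as.character(df$gene_id), essential = ess,
                    lethality_mode = mode, stringsAsFactors = FALSE)
  conflict <- tapply(tab$essential, tab$gene_id,
                     function(x) length(unique(x)) > 1)
  bad_genes <- names(conflict)[conflict]
  if (length(bad_genes) > 0) {
    log_msg(sprintf("discarding %d gene(s) with conflicting essentiality records",
                    length(bad_genes)), level = "WARN")
    tab <- tab[!(tab$gene_id %in% bad_genes), , drop = FALSE]
  }
  out <- tab[!duplicated(tab$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_conflicting") <- length(bad_genes)
  class(out) <- c("essentiality_table", "data.frame")
  out
}

#' Read a screen-linkage P-value table
#'
#' One row per (mutation, screen, transmission model) combination with its
#' Bonferroni-adjusted genotype-phenotype linkage P value.
#'
#' @param path TSV with columns `mutation_id`, `screen_id`, `model`
#'   (recessive / additive / dominant), `p_value` in (0, 1\].
#' @return Data frame of class `screen_linkage_table`.
#' @export
read_screen_linkage <- function(path) {
  df <- read_tsv_checked(path, c("mutation_id", "screen_id", "model", "p_value"),
                         "screen linkage")
  what <- sprintf("screen linkage (%s)", path)
  check_closed_set(df$model, c("recessive", "additive", "dominant"),
                   "model", what)
  p <- parse_num(df$p_value, "p_value", what)
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop_fmt("%s: p_value must lie in (0, 1]; offending line(s) %s", what,
             paste(line_no(which(is.na(p) | p <= 0 | p > 1)), collapse = ", "))
  out <- data.frame(mutation_id = as.character(df$mutation_id),
                    screen_id = as.character(df$screen_id),
                    model = as.character(df$model),
                    p_value = p, stringsAsFactors = FALSE)
  class(out) <- c("screen_linkage_table", "data.frame")
  out
}

#' Write a table in the package's TSV dialect
#'
#' Tab-delimited, UTF-8, header row, "." for absent values. A read of the
#' written file with the matching reader reproduces the records
#' field-identically.
#'
#' @param x A data frame (any of the package's table classes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = NA_TOKEN, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read pipeline parameters from a YAML config
#'
#' Convenience wrapper: reads a YAML mapping and (optionally) extracts a
#' per-class damage-probability map under the key `damage_map`, validated
#' against the closed class set.
#'
#' @param path Path to a YAML file.
#' @return Named list of parameters; if a `damage_map` key is present it is
#'   returned as a validated named numeric vector.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$damage_map)) {
    cfg$damage_map <- validate_damage_map(unlist(cfg$damage_map))
  }
  cfg
}

#' @rdname read_config
#' @param map Named numeric vector, one entry per mutation class, values in
#'   \[0, 1\].
#' @export
validate_damage_map <- function(map) {
  missing <- setdiff(mutation_classes(), names(map))
  if (length(missing) > 0)
    stop_fmt("damage map is missing class(es): %s", paste(missing, collapse = ", "))
  map <- map[mutation_classes()]
  if (any(!is.finite(map) | map < 0 | map > 1))
    stop_fmt("damage map values must lie in [0, 1]")
  map
}
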