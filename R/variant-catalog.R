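## Variant catalog: parse, merge, deduplicate and classify missense variants
## from ClinVar-, Humsavar-, Ensembl- and gnomAD-style tabular exports.

VARIANT_SOURCES <- c("clinvar", "humsavar", "ensembl", "gnomad")
VARIANT_CLASSES <- c("LPP", "BENIGN", "VUS", "CIP", "EXCLUDED")

#' Allele-frequency threshold above which a population variant absent from
#' ClinVar is considered benign.
#' @export
BENIGN_AF_THRESHOLD <- 0.00005

#' Parse a compact missense-variant label
#'
#' Accepts the usual `<ref><position><alt>` protein notation with one- or
#' three-letter residue codes (e.g. `"R437W"`, `"Arg437Trp"`). Parsing and
#' re-formatting with [format_variant_label()] round-trips one-letter input.
#'
#' @param label Character vector of labels.
#' @return A data.frame with columns `ref_aa`, `position`, `alt_aa`
#'   (one-letter codes, 1-based integer position).
#' @examples
#' parse_variant_label("R437W")
#' @export
parse_variant_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]{1}|[A-Za-z]{3})([0-9]+)([A-Za-z]{1}|[A-Za-z]{3})$", label))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed variant label: ", paste(unique(label[bad]), collapse = ", "))
  }
  ref <- aa_one_letter(vapply(m, `[`, "", 2L))
  pos <- as.integer(vapply(m, `[`, "", 3L))
  alt <- aa_one_letter(vapply(m, `[`, "", 4L))
  if (any(pos < 1L)) stop("protein positions are 1-based; got position 0")
  if (any(ref == alt)) {
    stop("synonymous label (ref == alt): ",
         paste(unique(label[ref == alt]), collapse = ", "))
  }
  data.frame(ref_aa = ref, position = pos, alt_aa = alt, stringsAsFactors = FALSE)
}

#' @rdname parse_variant_label
#' @param ref_aa,position,alt_aa Parsed components.
#' @export
format_variant_label <- function(ref_aa, position, alt_aa) {
  paste0(ref_aa, position, alt_aa)
}

## Map a free-text clinical-significance string to a coarse class.
normalize_significance <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("OTHER", length(x))
  out[grepl("pathogenic", x)] <- "LPP"
  out[x %in% c("p", "lp", "lp/p", "likely pathogenic", "pathogenic")] <- "LPP"
  out[grepl("benign", x)] <- "BENIGN"
  out[grepl("uncertain", x)] <- "VUS"
  out[grepl("conflicting", x)] <- "CIP"
  out[is.na(x) | x == ""] <- "OTHER"
  out
}

#' Benign classification rule
#'
#' A variant is benign iff its population allele frequency strictly exceeds
#' `af_threshold` and it has no ClinVar record. Variants with no reported
#' frequency are never benign.
#'
#' @param af Allele frequency in `[0, 1]`, or `NA` when absent.
#' @param present_in_clinvar Logical; does any ClinVar record exist?
#' @param af_threshold Frequency threshold (default `5e-5`, strict `>`).
#' @return Logical vector.
#' @export
classify_benign <- function(af, present_in_clinvar, af_threshold = BENIGN_AF_THRESHOLD) {
  !is.na(af) & af > af_threshold & !present_in_clinvar
}

#' Likely-pathogenic/pathogenic classification rule
#'
#' A variant is LP/P when Humsavar or Ensembl report it as likely
#' pathogenic/pathogenic, or when ClinVar reports it LP/P together with a
#' non-empty specific clinical condition. Any ClinVar record calling the
#' variant benign/likely-benign or of uncertain significance vetoes the
#' LP/P class.
#'
#' @param source Character vector of source databases for the records of
#'   one variant (`"clinvar"`, `"humsavar"`, `"ensembl"`, `"gnomad"`).
#' @param clinical_significance Reported class strings, parallel to `source`.
#' @param condition Free-text condition strings, parallel to `source`.
#' @return Single logical.
#' @export
classify_lpp <- function(source, clinical_significance, condition = NULL) {
  if (length(source) == 0L) stop("no source records supplied")
  if (is.null(condition)) condition <- rep("", length(source))
  cls <- normalize_significance(clinical_significance)
  clin <- source == "clinvar"
  if (any(clin & cls %in% c("BENIGN", "VUS"))) return(FALSE)
  has_condition <- !is.na(condition) & nzchar(trimws(condition))
  lp_other <- any(source %in% c("humsavar", "ensembl") & cls == "LPP")
  lp_clin <- any(clin & cls == "LPP" & has_condition)
  lp_other || lp_clin
}

#' Read one tabular variant export
#'
#' @param path TSV/CSV file path.
#' @param source One of `"clinvar"`, `"humsavar"`, `"ensembl"`, `"gnomad"`.
#' @param column_map Optional named list mapping the standard column names
#'   (`gene`, `accession`, `protein_change`, `clinical_significance`,
#'   `condition`, `allele_frequency`) to the file's column names; entries
#'   may be omitted when the file already uses the standard name. A YAML
#'   file of per-dialect maps can be loaded with [yaml::read_yaml()].
#' @param sep Field separator (default tab).
#' @return A standardized data.frame with a `source` column.
#' @export
read_variant_table <- function(path, source, column_map = NULL, sep = "\t") {
  source <- match.arg(source, VARIANT_SOURCES)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE)
  std <- c("gene", "accession", "protein_change", "clinical_significance",
           "condition", "allele_frequency")
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (col in std) {
    from <- if (!is.null(column_map) && !is.null(column_map[[col]])) column_map[[col]] else col
    out[[col]] <- if (from %in% names(raw)) raw[[from]] else NA
  }
  out$allele_frequency <- suppressWarnings(as.numeric(out$allele_frequency))
  out$source <- source
  out
}

#' Assemble a classified variant catalog
#'
#' Merges per-source exports, deduplicates on (gene, position, ref, alt)
#' and assigns each merged record exactly one class among `LPP`, `BENIGN`,
#' `VUS`, `CIP`, `EXCLUDED` using the database rules: LP/P via
#' [classify_lpp()], VUS when a ClinVar significance contains "Uncertain
#' significance", CIP for ClinVar conflicting interpretations, benign via
#' [classify_benign()]. Records matching no rule are `EXCLUDED`. Records at
#' the same gene/position whose reference residues disagree across sources
#' are flagged `ref_conflict` rather than silently merged.
#'
#' @param tables List of standardized tables from [read_variant_table()]
#'   (or data.frames with the same columns plus `source`).
#' @param af_threshold Benign allele-frequency threshold.
#' @return A `variant_catalog` data.frame with columns `gene`, `accession`,
#'   `position`, `ref_aa`, `alt_aa`, `label`, `class`, `af`, `sources`,
#'   `conditions`, `flag`, sorted by gene, position, alt residue.
#' @export
assemble_catalog <- function(tables, af_threshold = BENIGN_AF_THRESHOLD) {
  if (is.data.frame(tables)) tables <- list(tables)
  all <- do.call(rbind, lapply(tables, function(t) {
    t[c("gene", "accession", "protein_change", "clinical_significance",
        "condition", "allele_frequency", "source")]
  }))
  if (is.null(all) || nrow(all) == 0L) {
    return(empty_catalog())
  }
  parsed <- parse_variant_label(all$protein_change)
  all <- cbind(all, parsed)
  key <- paste(all$gene, parsed$position, parsed$ref_aa, parsed$alt_aa, sep = "|")
  groups <- split(seq_len(nrow(all)), key)

  rows <- lapply(groups, function(idx) {
    g <- all[idx, , drop = FALSE]
    in_clinvar <- any(g$source == "clinvar")
    af <- suppressWarnings(max(g$allele_frequency, na.rm = TRUE))
    if (!is.finite(af)) af <- NA_real_
    cls_norm <- normalize_significance(g$clinical_significance)
    class <- if (classify_lpp(g$source, g$clinical_significance, g$condition)) {
      "LPP"
    } else if (any(g$source == "clinvar" & cls_norm == "CIP")) {
      "CIP"
    } else if (any(g$source == "clinvar" & cls_norm == "VUS")) {
      "VUS"
    } else if (classify_benign(af, in_clinvar, af_threshold)) {
      "BENIGN"
    } else {
      "EXCLUDED"
    }
    conds <- unique(g$condition[!is.na(g$condition) & nzchar(trimws(g$condition))])
    acc <- unique(g$accession[!is.na(g$accession)])
    data.frame(
      gene = g$gene[1L], accession = if (length(acc)) acc[1L] else NA_character_,
      position = g$position[1L], ref_aa = g$ref_aa[1L], alt_aa = g$alt_aa[1L],
      label = format_variant_label(g$ref_aa[1L], g$position[1L], g$alt_aa[1L]),
      class = class, af = af,
      sources = paste(sort(unique(g$source)), collapse = ","),
      conditions = paste(sort(conds), collapse = ";"),
      flag = "", stringsAsFactors = FALSE)
  })
  cat <- do.call(rbind, rows)

  ## flag reference-residue conflicts at a shared gene/position
  by_pos <- split(seq_len(nrow(cat)), paste(cat$gene, cat$position, sep = "|"))
  for (idx in by_pos) {
    if (length(unique(cat$ref_aa[idx])) > 1L) cat$flag[idx] <- "ref_conflict"
  }

  cat <- cat[order(cat$gene, cat$position, cat$alt_aa), , drop = FALSE]
  rownames(cat) <- NULL
  as_variant_catalog(cat)
}

empty_catalog <- function() {
  as_variant_catalog(data.frame(
    gene = character(), accession = character(), position = integer(),
    ref_aa = character(), alt_aa = character(), label = character(),
    class = character(), af = numeric(), sources = character(),
    conditions = character(), flag = character(), stringsAsFactors = FALSE))
}

as_variant_catalog <- function(df) {
  class(df) <- c("variant_catalog", "data.frame")
  attr(df, "catalog_hash") <- catalog_hash(df)
  df
}

## Stable content hash used to check that all pipeline stages ran on the
## same catalog.
catalog_hash <- function(df) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  core <- df[c("gene", "position", "ref_aa", "alt_aa", "class")]
  utils::write.table(core[do.call(order, core), ], tmp, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

#' @export
print.variant_catalog <- function(x, ...) {
  cat("Variant catalog:", nrow(x), "merged missense variants,",
      length(unique(x$gene)), "gene(s)\n")
  if (nrow(x)) print(table(class = x$class))
  invisible(x)
}

#' Per-gene class counts of a catalog
#'
#' @param catalog A `variant_catalog`.
#' @return Data.frame with one row per gene and columns `gene`,
#'   `accession`, `LPP`, `VUS`, `BENIGN` (the usual summary layout for a
#'   family-wide variant collection).
#' @export
catalog_counts <- function(catalog) {
  genes <- sort(unique(catalog$gene))
  out <- do.call(rbind, lapply(genes, function(g) {
    sub <- catalog[catalog$gene == g, ]
    data.frame(gene = g, accession = sub$accession[1L],
               LPP = sum(sub$class == "LPP"), VUS = sum(sub$class == "VUS"),
               BENIGN = sum(sub$class == "BENIGN"), stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(gene = character(), accession = character(),
                      LPP = integer(), VUS = integer(), BENIGN = integer())
  }
  rownames(out) <- NULL
  out
}

#' Write / read a catalog as TSV
#'
#' The round trip is exact: numeric allele frequencies are serialized at
#' full precision.
#'
#' @param catalog A `variant_catalog`.
#' @param path Output file.
#' @export
write_catalog <- function(catalog, path) {
  out <- as.data.frame(catalog)
  out$af <- ifelse(is.na(out$af), "NA", sprintf("%.17g", out$af))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = c(position = "integer", af = "character"))
  df$af <- as.numeric(df$af)
  for (col in c("sources", "conditions", "flag")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "", df[[col]])
  }
  as_variant_catalog(df)
}
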