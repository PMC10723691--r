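## Paralogue annotation: alignment position mapping, physicochemical column
## conservation (Zvelebil-style), and transfer of LP/P annotations onto the
## reference channel.

#' Construct or read a family alignment
#'
#' Sequences are gapped strings of equal width; ids should match the gene
#' symbols used in the variant catalog. The reference sequence is the
#' channel under study onto which paralogue annotations are mapped.
#'
#' @param sequences Named character vector of gapped sequences (gap `-`).
#' @param reference_id Id of the reference sequence; must be present.
#' @return A `paralogue_alignment` object.
#' @export
new_alignment <- function(sequences, reference_id) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  w <- unique(nchar(sequences))
  if (length(w) != 1L) stop("all gapped sequences must have equal length")
  if (!reference_id %in% names(sequences)) {
    stop("reference id '", reference_id, "' not among sequences")
  }
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(mat) <- names(sequences)
  structure(list(sequences = toupper(sequences), matrix = mat,
                 reference_id = reference_id, width = w),
            class = "paralogue_alignment")
}

#' @rdname new_alignment
#' @param path Aligned FASTA file.
#' @export
read_alignment <- function(path, reference_id) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  new_alignment(seqs, reference_id)
}

#' Write an alignment as aligned FASTA
#' @param alignment A `paralogue_alignment`.
#' @param path Output file.
#' @export
write_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(alignment$sequences)) {
    writeLines(c(paste0(">", nm), alignment$sequences[[nm]]), con)
  }
  invisible(path)
}

#' @export
print.paralogue_alignment <- function(x, ...) {
  cat("Alignment:", length(x$sequences), "sequences x", x$width,
      "columns; reference:", x$reference_id, "\n")
  invisible(x)
}

ungapped_length <- function(alignment, id) {
  sum(alignment$matrix[id, ] != "-")
}

## Column index of residue `pos` (1-based ungapped) of sequence `id`.
residue_column <- function(alignment, id, pos) {
  if (!id %in% rownames(alignment$matrix)) stop("unknown sequence id: ", id)
  row <- alignment$matrix[id, ]
  cum <- cumsum(row != "-")
  n <- cum[length(cum)]
  out <- rep(NA_integer_, length(pos))
  ok <- pos >= 1L & pos <= n
  if (any(!ok)) stop("position out of range for ", id, ": ",
                     paste(pos[!ok], collapse = ", "))
  out <- match(pos, cum)  # first column reaching each count is the residue
  out
}

## Ungapped position of sequence `id` at alignment column `col`, NA if gap.
column_position <- function(alignment, id, col) {
  row <- alignment$matrix[id, ]
  cum <- cumsum(row != "-")
  ifelse(row[col] == "-", NA_integer_, cum[col])
}

#' Map a residue position between aligned family members
#'
#' Follows the shared alignment column: residue `pos` of `from_id` maps to
#' the residue of `to_id` in the same column, or `NA` when `to_id` has a
#' gap there. The mapping is injective on its domain and round-trips.
#'
#' @param alignment A `paralogue_alignment`.
#' @param from_id Sequence carrying the query position.
#' @param pos Integer vector of 1-based ungapped positions in `from_id`.
#' @param to_id Target sequence (default: the reference).
#' @return Integer vector of positions in `to_id`, `NA` where unmapped.
#' @export
map_position <- function(alignment, from_id, pos, to_id = alignment$reference_id) {
  cols <- residue_column(alignment, from_id, pos)
  column_position(alignment, to_id, cols)
}

#' Physicochemical conservation score of an alignment column
#'
#' The score is the fraction of the ten physicochemical properties (see
#' [aa_property_table()]) whose truth value is identical across all
#' residues in the column: 1 for an identical (or property-equivalent)
#' column, 0 for no shared property state. Gaps are penalized: a column
#' containing any gap scores 0, since a gap agrees with no residue on any
#' property.
#'
#' @param column Character vector of one-letter residues (may contain `-`).
#' @param table Property truth table (default [aa_property_table()]).
#' @return Conservation score in `[0, 1]`.
#' @export
conservation_score <- function(column, table = aa_property_table()) {
  if (length(column) == 0L) stop("empty alignment column")
  column <- toupper(column)
  if (any(column %in% c("-", ".", ""))) return(0)
  bad <- !column %in% rownames(table)
  if (any(bad)) stop("unknown residue(s) in column: ",
                     paste(unique(column[bad]), collapse = ", "))
  sub <- table[column, , drop = FALSE]
  agree <- colSums(sub) %in% c(0L, nrow(sub))
  mean(agree)
}

#' Per-column conservation track of an alignment
#'
#' @param alignment A `paralogue_alignment`.
#' @param table Property truth table.
#' @return Data.frame with `column`, `ref_position` (reference residue
#'   index at that column, `NA` under a reference gap) and `cs`.
#' @export
conservation_track <- function(alignment, table = aa_property_table()) {
  m <- alignment$matrix
  cs <- apply(m, 2L, conservation_score, table = table)
  data.frame(column = seq_len(ncol(m)),
             ref_position = column_position(alignment, alignment$reference_id,
                                            seq_len(ncol(m))),
             cs = unname(cs))
}

#' Transfer paralogue LP/P annotations onto the reference channel
#'
#' Every LP/P variant of a paralogue whose position maps through the
#' alignment to a reference residue in a column with conservation score
#' strictly above `cs_threshold` is emitted as a transfer; reference
#' variants recorded at that position (typically VUSs) are attached as the
#' candidates the transfer supports. Paralogues in the catalog but absent
#' from the alignment are skipped with a warning.
#'
#' @param catalog A `variant_catalog` containing paralogue LPP records.
#' @param alignment A `paralogue_alignment` whose ids are gene symbols.
#' @param cs_threshold Conservation gate (default 0.3, strict `>`).
#' @param table Property truth table.
#' @return A `paralogue_transfers` data.frame: `ref_position`, `ref_aa`,
#'   `paralogue`, `paralogue_variant`, `paralogue_position`, `cs`,
#'   `ref_variants` (comma-joined labels of reference-catalog variants at
#'   the position, `""` if none).
#' @export
transfer_lpp <- function(catalog, alignment, cs_threshold = 0.3,
                         table = aa_property_table()) {
  ref_gene <- alignment$reference_id
  lpp <- catalog[catalog$class == "LPP" & catalog$gene != ref_gene, , drop = FALSE]
  known <- lpp$gene %in% names(alignment$sequences)
  if (any(!known)) {
    warning("paralogue(s) not in alignment, skipped: ",
            paste(unique(lpp$gene[!known]), collapse = ", "))
    lpp <- lpp[known, , drop = FALSE]
  }
  track <- conservation_track(alignment, table)
  ref_rows <- catalog[catalog$gene == ref_gene, , drop = FALSE]

  out <- lapply(seq_len(nrow(lpp)), function(i) {
    g <- lpp$gene[i]; p <- lpp$position[i]
    if (p > ungapped_length(alignment, g)) {
      warning("variant ", lpp$label[i], " beyond ", g, " aligned length; skipped")
      return(NULL)
    }
    col <- residue_column(alignment, g, p)
    ref_pos <- column_position(alignment, ref_gene, col)
    if (is.na(ref_pos)) return(NULL)
    cs <- track$cs[col]
    if (!(cs > cs_threshold)) return(NULL)
    at_pos <- ref_rows[ref_rows$position == ref_pos, , drop = FALSE]
    data.frame(ref_position = ref_pos,
               ref_aa = alignment$matrix[ref_gene, col],
               paralogue = g, paralogue_variant = lpp$label[i],
               paralogue_position = p, cs = cs,
               ref_variants = paste(at_pos$label, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(ref_position = integer(), ref_aa = character(),
                      paralogue = character(), paralogue_variant = character(),
                      paralogue_position = integer(), cs = numeric(),
                      ref_variants = character(), stringsAsFactors = FALSE)
  }
  res <- res[order(res$ref_position, res$paralogue, res$paralogue_variant), ]
  rownames(res) <- NULL
  class(res) <- c("paralogue_transfers", "data.frame")
  attr(res, "cs_threshold") <- cs_threshold
  attr(res, "catalog_hash") <- attr(catalog, "catalog_hash")
  res
}

#' @export
print.paralogue_transfers <- function(x, ...) {
  cat("Paralogue transfers:", nrow(x), "LP/P variant(s) onto",
      length(unique(x$ref_position)), "reference position(s) (Cs >",
      attr(x, "cs_threshold"), ")\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}
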