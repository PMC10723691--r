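## Seeded synthetic-data generator. Emulates all four pipeline inputs:
## class-labelled variant exports, predictor score tables with controlled
## class separation, a family alignment with planted conserved/divergent
## columns and paralogue LP/P variants, and a toy tetramer structure with
## planted inter-residue distances. One master seed with fixed per-generator
## substreams keeps every artifact independently reproducible.

sim_substream <- function(seed, k) set.seed(as.integer(seed) + k * 1000003L)

#' Default per-gene variant counts of the simulated family
#'
#' The family layout used as the generator default: eight TRP-superfamily
#' channels with the likely-pathogenic/pathogenic, uncertain and benign
#' missense counts observed in the public databases for this family
#' (130 LP/P, 1117 VUS and 103 benign in total; 565 VUS on the reference
#' channel TRPM4).
#'
#' @return Data.frame `gene`, `accession`, `n_lpp`, `n_vus`, `n_benign`.
#' @export
default_sim_genes <- function() {
  data.frame(
    gene = c("TRPA1", "TRPC6", "TRPM1", "TRPM4", "TRPM6", "TRPM7", "TRPV4", "TRPV6"),
    accession = c("O75762", "Q9Y210", "Q7Z4N2", "Q8TD43", "Q9BX84", "Q96QT4",
                  "Q9HBA0", "Q9H1D0"),
    n_lpp = c(1L, 17L, 22L, 10L, 1L, 1L, 72L, 6L),
    n_vus = c(31L, 90L, 18L, 565L, 7L, 29L, 349L, 28L),
    n_benign = c(36L, 10L, 4L, 6L, 3L, 42L, 0L, 2L),
    stringsAsFactors = FALSE)
}

#' Default simulated predictor panel
#'
#' One row per predictor with the target class separation (an AUC-like
#' concordance), the score orientation and the published deleterious
#' threshold with the tool's natural score range. Scores are drawn from two
#' unit-variance Gaussians whose mean separation delta satisfies
#' `pnorm(delta / sqrt(2)) = auc`, then mapped monotonically onto the
#' tool's scale so that the configured threshold sits at the class
#' boundary.
#'
#' @return Data.frame `tool`, `auc`, `direction`, `threshold`, `lo`, `hi`.
#' @export
default_sim_tools <- function() {
  g <- "damaging_if_greater"; l <- "damaging_if_less"
  df <- rbind(
    data.frame(tool = "ClinPred", auc = 0.90, direction = g, threshold = 0.6, lo = 0, hi = 1),
    data.frame(tool = "VEST4", auc = 0.88, direction = g, threshold = 0.65, lo = 0, hi = 1),
    data.frame(tool = "MCap", auc = 0.87, direction = g, threshold = 0.05, lo = 0, hi = 1),
    data.frame(tool = "REVEL", auc = 0.86, direction = g, threshold = 0.45, lo = 0, hi = 1),
    data.frame(tool = "PrimateAI", auc = 0.86, direction = g, threshold = 0.6, lo = 0, hi = 1),
    data.frame(tool = "MVP", auc = 0.84, direction = g, threshold = 0.7, lo = 0, hi = 1),
    data.frame(tool = "MetaSVM", auc = 0.82, direction = g, threshold = 0, lo = -2, hi = 2),
    data.frame(tool = "MetaLR", auc = 0.80, direction = g, threshold = 0.4, lo = 0, hi = 1),
    data.frame(tool = "LIST.S2", auc = 0.80, direction = g, threshold = 0.85, lo = 0, hi = 1),
    data.frame(tool = "DEOGEN2", auc = 0.80, direction = g, threshold = 0.4, lo = 0, hi = 1),
    data.frame(tool = "FATHMM", auc = 0.77, direction = l, threshold = -1, lo = -10, hi = 10),
    data.frame(tool = "PPH_HDIV", auc = 0.76, direction = g, threshold = 0.45, lo = 0, hi = 1),
    data.frame(tool = "CADD", auc = 0.75, direction = g, threshold = 3, lo = -8, hi = 20),
    data.frame(tool = "PPH_HVAR", auc = 0.74, direction = g, threshold = 0.45, lo = 0, hi = 1),
    data.frame(tool = "SIFT4G", auc = 0.73, direction = l, threshold = 0.05, lo = 0, hi = 1),
    data.frame(tool = "DANN", auc = 0.72, direction = g, threshold = 0.99, lo = 0, hi = 1),
    data.frame(tool = "SIFT", auc = 0.72, direction = l, threshold = 0.0045, lo = 0, hi = 1),
    data.frame(tool = "PROVEAN", auc = 0.71, direction = l, threshold = -1.5, lo = -14, hi = 14),
    data.frame(tool = "MutationAssessor", auc = 0.71, direction = g, threshold = 1.7, lo = -6, hi = 6),
    data.frame(tool = "LRT", auc = 0.70, direction = l, threshold = 1e-4, lo = 0, hi = 1),
    data.frame(tool = "MutationTaster", auc = 0.68, direction = g, threshold = 1, lo = 0, hi = 2),
    data.frame(tool = "GenoCanyon", auc = 0.62, direction = g, threshold = 0.7, lo = 0, hi = 1))
  df$missing <- 0
  df
}

#' Default planted contact layout of the toy tetramer
#'
#' Pairs are planted between topology segments of the shipped TRPM4 segment
#' map: 16 transmembrane/extracellular pairs and 24 cytoplasmic pairs
#' below the 5-Angstrom cutoff (matching the scale at which such contact
#' analyses operate), plus 10 pairs planted beyond the cutoff as negative
#' controls.
#'
#' @return Data.frame `seg_a`, `seg_b`, `relation`, `n`, `d_lo`, `d_hi`.
#' @export
default_contact_layout <- function() {
  near <- function(a, b, rel, n) data.frame(seg_a = a, seg_b = b, relation = rel,
                                            n = n, d_lo = 3.6, d_hi = 4.9,
                                            stringsAsFactors = FALSE)
  far <- function(a, b, rel, n) data.frame(seg_a = a, seg_b = b, relation = rel,
                                           n = n, d_lo = 5.5, d_hi = 9.0,
                                           stringsAsFactors = FALSE)
  rbind(near("S1", "S4", "intra", 3), near("S2", "S4", "intra", 1),
        near("S3", "S4", "intra", 1), near("S4", "S5", "inter", 4),
        near("S1", "S5", "inter", 2), near("S5", "P1", "intra", 2),
        near("P1", "P2", "intra", 2), near("S5", "S6", "intra", 1),
        near("MHR1/2", "MHR3", "intra", 10), near("MHR3", "MHR4", "intra", 6),
        near("MHR4", "TRP helix", "intra", 4),
        near("S4-S5 linker", "TRP helix", "intra", 2),
        near("MHR4", "CTD", "intra", 2),
        far("S1", "S2", "intra", 4), far("MHR1/2", "MHR4", "intra", 6))
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic study in one validated list. The
#' defaults reproduce the study conditions: the family-wide class counts of
#' [default_sim_genes()], the predictor separations of
#' [default_sim_tools()], 63 transferable paralogue LP/P variants on 36
#' reference positions (50 reference VUSs and one benign variant sitting on
#' those positions), and the contact layout of [default_contact_layout()].
#'
#' @param seed Master integer seed.
#' @param genes Per-gene counts (see [default_sim_genes()]).
#' @param reference_gene Reference channel symbol.
#' @param seq_length Reference sequence length (default 1214).
#' @param tools Predictor panel (see [default_sim_tools()]).
#' @param vus_pathogenic_fraction Fraction of VUSs drawn from the
#'   pathogenic score component (latent mixture, default 0.55).
#' @param n_transfer_variants,n_transfer_positions Planted transferable
#'   paralogue LP/P variants and the distinct reference positions they map
#'   to.
#' @param n_unmapped_lpp Paralogue LP/P variants planted on columns where
#'   the reference is gapped (never transfer).
#' @param n_ref_vus_at_transfers Reference VUSs planted on transfer
#'   positions.
#' @param n_veto Reference variants planted as Humsavar-LP but
#'   ClinVar-uncertain (the ClinVar veto keeps them VUS).
#' @param af_range Benign allele-frequency range (low, high], strictly
#'   above the benign threshold.
#' @param contact_layout Planted structural pairs (see
#'   [default_contact_layout()]).
#' @param segmap Segment map used for planting and analysis.
#' @param gate_tool Predictor used for the high-score gate.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, genes = default_sim_genes(),
                       reference_gene = "TRPM4", seq_length = 1214,
                       tools = default_sim_tools(),
                       vus_pathogenic_fraction = 0.55,
                       n_transfer_variants = 63, n_transfer_positions = 36,
                       n_unmapped_lpp = 12, n_ref_vus_at_transfers = 50,
                       n_veto = 1, af_range = c(5e-5, 1e-3),
                       contact_layout = default_contact_layout(),
                       segmap = read_segment_map(),
                       gate_tool = "ClinPred") {
  stopifnot(reference_gene %in% genes$gene,
            all(genes$n_lpp >= 0), all(genes$n_vus >= 0), all(genes$n_benign >= 0),
            all(tools$auc >= 0.5), all(tools$auc <= 1),
            n_transfer_variants >= n_transfer_positions,
            af_range[1] >= BENIGN_AF_THRESHOLD, af_range[2] > af_range[1])
  structure(list(seed = as.integer(seed), genes = genes,
                 reference_gene = reference_gene, seq_length = seq_length,
                 tools = tools,
                 vus_pathogenic_fraction = vus_pathogenic_fraction,
                 n_transfer_variants = n_transfer_variants,
                 n_transfer_positions = n_transfer_positions,
                 n_unmapped_lpp = n_unmapped_lpp,
                 n_ref_vus_at_transfers = n_ref_vus_at_transfers,
                 n_veto = n_veto, af_range = af_range,
                 contact_layout = contact_layout, segmap = segmap,
                 gate_tool = gate_tool),
            class = "sim_config")
}

## Divergent-column residue set: any column mixing these four residues
## agrees on at most two of the ten properties (Cs <= 0.2).
DIVERGENT_SET <- c("W", "D", "G", "P")

#' Generate the family alignment with planted conservation structure
#'
#' Builds an alignment of the configured genes over the reference length:
#' background columns are fully conserved (Cs = 1); each paralogue carries
#' a private gap block (so coordinate mapping is exercised); a block of
#' reference-gap columns holds paralogue insertions; planted divergent
#' columns (Cs <= 0.2) host the non-transferable paralogue LP/P variants;
#' and transferable paralogue LP/P variants sit in conserved columns at
#' the planted reference positions.
#'
#' @param config A `sim_config`.
#' @return List with `alignment` (a `paralogue_alignment`),
#'   `paralogue_lpp` (planted LP/P variants with their expected mapping),
#'   and `transfer_positions` (reference positions expected to receive
#'   transfers).
#' @export
gen_alignment <- function(config) {
  sim_substream(config$seed, 3L)
  L <- config$seq_length
  genes <- config$genes$gene
  ref <- config$reference_gene
  paralogues <- setdiff(genes, ref)

  n_refgap <- 24L
  W <- L + n_refgap
  refgap_cols <- seq(41L, by = 2L, length.out = n_refgap)  # interleaved inserts
  ref_cols <- setdiff(seq_len(W), refgap_cols)             # column of ref residue i

  ref_seq <- sample(AA_ONE, L, replace = TRUE)
  mat <- matrix("", nrow = length(genes), ncol = W, dimnames = list(genes, NULL))
  for (g in genes) {
    mat[g, ref_cols] <- ref_seq
    mat[g, refgap_cols] <- sample(AA_ONE, n_refgap, replace = TRUE)
  }
  mat[ref, refgap_cols] <- "-"

  ## private gap block per paralogue (shifts its numbering)
  gap_cols <- integer(0)
  for (k in seq_along(paralogues)) {
    block <- ref_cols[200L + 30L * (k - 1L) + seq_len(15L)]
    mat[paralogues[k], block] <- "-"
    gap_cols <- c(gap_cols, block)
  }

  usable <- setdiff(ref_cols, c(gap_cols, refgap_cols))
  usable <- usable[usable > max(refgap_cols)]  # keep planted columns clear of inserts
  ref_pos_of_col <- match(usable, ref_cols)

  ## transferable columns: conserved, one per planted reference position
  pick <- sample(seq_along(usable), config$n_transfer_positions)
  transfer_cols <- usable[pick]
  transfer_positions <- sort(ref_pos_of_col[pick])
  transfer_cols <- ref_cols[transfer_positions]

  ## divergent columns for sub-threshold paralogue variants
  n_para_lpp <- sum(config$genes$n_lpp[config$genes$gene != ref])
  n_divergent <- max(n_para_lpp - config$n_transfer_variants - config$n_unmapped_lpp, 0L)
  left <- setdiff(usable, transfer_cols)
  divergent_cols <- sort(sample(left, n_divergent))
  for (col in divergent_cols) {
    mat[, col] <- rep(DIVERGENT_SET, length.out = length(genes))
  }

  ## allocate paralogue LP/P variants: transferable first, round-robin over
  ## paralogues weighted by their planted counts
  avail <- stats::setNames(config$genes$n_lpp[match(paralogues, config$genes$gene)],
                           paralogues)
  slots <- rep(names(avail), avail)
  slots <- sample(slots)
  take <- function(n) {
    if (n == 0L) return(character(0))
    out <- slots[seq_len(n)]
    slots <<- slots[-seq_len(n)]
    out
  }
  n_tr <- min(config$n_transfer_variants, length(slots))
  tr_genes <- take(n_tr)
  tr_cols <- c(transfer_cols,
               sample(transfer_cols, max(n_tr - length(transfer_cols), 0L),
                      replace = TRUE))[seq_len(n_tr)]
  n_un <- min(config$n_unmapped_lpp, length(slots))
  un_genes <- take(n_un)
  un_cols <- refgap_cols[seq_len(n_un)]
  dv_genes <- take(length(slots))
  dv_cols <- divergent_cols[seq_along(dv_genes)]

  plant <- data.frame(gene = c(tr_genes, un_genes, dv_genes),
                      column = c(tr_cols, un_cols, dv_cols),
                      transferable = c(rep(TRUE, length(tr_genes)),
                                       rep(FALSE, length(un_genes) + length(dv_genes))),
                      stringsAsFactors = FALSE)

  aln <- new_alignment(apply(mat, 1L, paste, collapse = ""), ref)
  para_pos <- vapply(seq_len(nrow(plant)), function(i) {
    column_position(aln, plant$gene[i], plant$column[i])
  }, 1L)
  ref_pos <- column_position(aln, ref, plant$column)
  ref_aa <- vapply(seq_len(nrow(plant)), function(i) mat[plant$gene[i], plant$column[i]], "")
  ## distinct alt residues within each (gene, column) so no two planted
  ## variants coincide
  alt_aa <- character(nrow(plant))
  for (grp in split(seq_len(nrow(plant)), paste(plant$gene, plant$column))) {
    alt_aa[grp] <- sample(setdiff(AA_ONE, ref_aa[grp][1L]), length(grp))
  }
  plant$position <- para_pos
  plant$ref_aa <- ref_aa
  plant$alt_aa <- alt_aa
  plant$label <- format_variant_label(ref_aa, para_pos, alt_aa)
  plant$expected_ref_position <- ifelse(plant$transferable, ref_pos, NA_integer_)

  list(alignment = aln, paralogue_lpp = plant,
       transfer_positions = transfer_positions,
       ref_seq = mat[ref, ref_cols])  # after divergent-column planting
}

#' Generate source variant tables
#'
#' Emits ClinVar-, Humsavar-, Ensembl- and gnomAD-style standardized tables
#' that assemble into a catalog with exactly the configured class counts.
#' Benign allele frequencies lie strictly above the benign threshold;
#' `n_veto` reference VUSs additionally carry a Humsavar LP record that the
#' ClinVar veto overrides.
#'
#' @param config A `sim_config`.
#' @param alignment Optional result of [gen_alignment()]; when supplied,
#'   paralogue LP/P variants are the planted ones and reference residues
#'   are read from the generated sequences.
#' @param ref_vus_positions Optional integer vector of reference positions
#'   that must host VUSs (duplicates allowed: two alt residues at one
#'   position).
#' @param ref_benign_positions Optional reference positions for benign
#'   variants.
#' @return List of four standardized tables (`clinvar`, `humsavar`,
#'   `ensembl`, `gnomad`).
#' @export
gen_variant_tables <- function(config, alignment = NULL,
                               ref_vus_positions = NULL,
                               ref_benign_positions = NULL) {
  sim_substream(config$seed, 1L)
  ref <- config$reference_gene
  conditions <- c("Progressive familial heart block type IB",
                  "Cardiovascular phenotype", "Brugada syndrome")
  rows <- list()
  add <- function(source, gene, acc, label, sig, cond = "", af = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene = gene, accession = acc, protein_change = label,
      clinical_significance = sig, condition = cond, allele_frequency = af,
      source = source, stringsAsFactors = FALSE)
  }

  residue_at <- function(gene, pos) {
    if (length(pos) == 0L) return(character(0))
    if (is.null(alignment)) return(sample(AA_ONE, length(pos), replace = TRUE))
    seq <- gsub("-", "", alignment$alignment$sequences[[gene]])
    substring(seq, pos, pos)
  }
  gene_length <- function(gene) {
    if (is.null(alignment)) config$seq_length
    else nchar(gsub("-", "", alignment$alignment$sequences[[gene]]))
  }

  for (gi in seq_len(nrow(config$genes))) {
    g <- config$genes$gene[gi]; acc <- config$genes$accession[gi]
    n_lpp <- config$genes$n_lpp[gi]; n_vus <- config$genes$n_vus[gi]
    n_ben <- config$genes$n_benign[gi]
    L <- gene_length(g)

    ## LP/P variants
    if (g != ref && !is.null(alignment)) {
      lpp <- alignment$paralogue_lpp[alignment$paralogue_lpp$gene == g, , drop = FALSE]
      lpp_pos <- lpp$position; lpp_ref <- lpp$ref_aa; lpp_alt <- lpp$alt_aa
    } else {
      lpp_pos <- sample(seq_len(L), n_lpp)
      lpp_ref <- residue_at(g, lpp_pos)
      lpp_alt <- vapply(lpp_ref, function(a) sample(setdiff(AA_ONE, a), 1L), "")
    }
    used <- lpp_pos
    lpp_lab <- format_variant_label(lpp_ref, lpp_pos, lpp_alt)
    for (i in seq_along(lpp_lab)) {
      src <- c("humsavar", "ensembl", "clinvar")[(i %% 3L) + 1L]
      if (src == "clinvar") {
        add("clinvar", g, acc, lpp_lab[i], "Pathogenic",
            conditions[(i %% length(conditions)) + 1L])
      } else {
        add(src, g, acc, lpp_lab[i], "Likely pathogenic")
      }
      if (i %% 5L == 0L) add("ensembl", g, acc, lpp_lab[i], "Pathogenic")
    }

    ## VUS
    planted <- if (g == ref && !is.null(ref_vus_positions)) ref_vus_positions else integer(0)
    n_rand <- n_vus - length(planted)
    stopifnot(n_rand >= 0)
    rand_pos <- sample(setdiff(seq_len(L), c(used, planted)), n_rand)
    vus_pos <- c(planted, rand_pos)
    used <- c(used, vus_pos)
    vus_ref <- residue_at(g, vus_pos)
    vus_alt <- character(length(vus_pos))
    for (i in seq_along(vus_pos)) {
      prior <- vus_alt[seq_len(i - 1L)][vus_pos[seq_len(i - 1L)] == vus_pos[i]]
      vus_alt[i] <- sample(setdiff(AA_ONE, c(vus_ref[i], prior)), 1L)
    }
    vus_lab <- format_variant_label(vus_ref, vus_pos, vus_alt)
    for (i in seq_along(vus_lab)) {
      add("clinvar", g, acc, vus_lab[i], "Uncertain significance")
      if (g == ref && i <= config$n_veto) {
        add("humsavar", g, acc, vus_lab[i], "Likely pathogenic")
      }
    }

    ## benign (gnomAD only, AF strictly above threshold)
    planted_b <- if (g == ref && !is.null(ref_benign_positions)) ref_benign_positions else integer(0)
    n_rand_b <- n_ben - length(planted_b)
    stopifnot(n_rand_b >= 0)
    ben_pos <- c(planted_b, sample(setdiff(seq_len(L), used), n_rand_b))
    ben_ref <- residue_at(g, ben_pos)
    ben_alt <- vapply(ben_ref, function(a) sample(setdiff(AA_ONE, a), 1L), "")
    af <- stats::runif(length(ben_pos), config$af_range[1], config$af_range[2])
    af <- pmax(af, config$af_range[1] * 1.0001)  # strictly above the threshold
    ben_lab <- format_variant_label(ben_ref, ben_pos, ben_alt)
    for (i in seq_along(ben_lab)) {
      add("gnomad", g, acc, ben_lab[i], "", af = af[i])
    }
  }

  all <- do.call(rbind, rows)
  if (is.null(all)) return(stats::setNames(list(), character(0)))
  split_src <- split(all, all$source)
  lapply(split_src[intersect(VARIANT_SOURCES, names(split_src))], function(d) {
    rownames(d) <- NULL
    d
  })
}

#' Generate a predictor score table
#'
#' Per tool, scores are drawn from two unit-variance Gaussians whose mean
#' separation yields the configured concordance (`pnorm(delta/sqrt(2)) =
#' auc`). LP/P variants draw from the pathogenic component and benign
#' variants from the neutral one; VUS (and other unlabelled) records draw
#' from a latent mixture shared across tools, with
#' `vus_pathogenic_fraction` of them pathogenic. Gaussian draws are mapped
#' monotonically onto each tool's score scale so that the configured
#' threshold sits at the class boundary (AUC is invariant under the map).
#'
#' @param config A `sim_config`.
#' @param catalog The assembled `variant_catalog`.
#' @param forced_pathogenic_positions Reference-gene positions whose VUSs
#'   are forced to the pathogenic latent component (used to emulate
#'   high-scoring candidate residues).
#' @return Score table: data.frame `variant_id` + one numeric column per
#'   tool.
#' @export
gen_scores <- function(config, catalog, forced_pathogenic_positions = NULL) {
  sim_substream(config$seed, 2L)
  n <- nrow(catalog)
  latent <- ifelse(catalog$class == "LPP", 1L,
                   ifelse(catalog$class == "BENIGN", 0L, NA_integer_))
  mix <- is.na(latent)
  latent[mix] <- stats::rbinom(sum(mix), 1L, config$vus_pathogenic_fraction)
  if (!is.null(forced_pathogenic_positions)) {
    forced <- catalog$gene == config$reference_gene &
      catalog$position %in% forced_pathogenic_positions & catalog$class == "VUS"
    latent[forced] <- 1L
  }

  out <- data.frame(variant_id = variant_id(catalog), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(config$tools))) {
    t <- config$tools[i, ]
    delta <- min(sqrt(2) * stats::qnorm(t$auc), 8)  # target 1 -> near-perfect
    z <- stats::rnorm(n, mean = delta * latent, sd = 1)
    p <- stats::pnorm(z - delta / 2)
    up <- p >= 0.5
    score <- numeric(n)
    if (t$direction == "damaging_if_greater") {
      score[up] <- t$threshold + (2 * p[up] - 1) * (t$hi - t$threshold)
      score[!up] <- t$threshold + (2 * p[!up] - 1) * (t$threshold - t$lo)
    } else {
      score[up] <- t$threshold - (2 * p[up] - 1) * (t$threshold - t$lo)
      score[!up] <- t$threshold - (2 * p[!up] - 1) * (t$hi - t$threshold)
    }
    if (t$missing > 0) {
      score[stats::runif(n) < t$missing] <- NA_real_
    }
    out[[t$tool]] <- score
  }
  out
}

#' Write a score table as TSV
#' @param scores Score table from [gen_scores()].
#' @param path Output file.
#' @export
write_score_table <- function(scores, path) {
  out <- scores
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in setdiff(names(df), "variant_id")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df
}

#' Generate a toy tetramer structure with planted sidechain distances
#'
#' Builds a four-chain structure from idealized residue geometry. Each
#' requested pair is placed as an isolated island: the partner residue is
#' rigid-body translated until the minimum sidechain heavy-atom distance
#' equals the requested value (solved numerically to < 0.001 Angstrom).
#' Intra-subunit pairs are replicated in all four chains; inter-subunit
#' pairs place the partner's copy from the adjacent chain next to the
#' first chain's residue. Unpaired positions are placed isolated. Glycine
#' in a planted pair is an infeasible request (no sidechain heavy atoms)
#' and raises an error.
#'
#' @param pairs Data.frame `pos_a`, `pos_b`, `distance`, `relation`
#'   (`"intra"`/`"inter"`).
#' @param residues Named character vector mapping position to one-letter
#'   residue type (every planted and extra position must appear).
#' @param extra_positions Positions placed without any partner.
#' @param file Optional path; when given, the structure is also written as
#'   PDB.
#' @return List with `model` (a `structure_model`), `ground_truth` (the
#'   planted pairs with their realized distances) and `file`.
#' @export
gen_structure <- function(pairs, residues, extra_positions = integer(0),
                          file = NULL) {
  chains <- c("A", "B", "C", "D")
  chain_off <- stats::setNames(lapply(0:3, function(i) c(0, 0, 300 * i)), chains)
  templates <- split(aa_atom_templates, aa_atom_templates$resid)

  res_tmpl <- function(pos) {
    one <- residues[[as.character(pos)]]
    if (is.null(one) || is.na(one)) stop("no residue type for position ", pos)
    templates[[AA_THREE[[one]]]]
  }
  sidechain_xyz <- function(tmpl) {
    sc <- tmpl[!(tmpl$elety %in% BACKBONE_ATOMS), , drop = FALSE]
    as.matrix(sc[c("x", "y", "z")])
  }

  atoms <- list()
  put <- function(pos, tmpl, origin, chain) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      chain = chain, resno = as.integer(pos),
      resid = tmpl$resid[1L], elety = tmpl$elety,
      x = tmpl$x + origin[1], y = tmpl$y + origin[2], z = tmpl$z + origin[3],
      o = 1, stringsAsFactors = FALSE)
  }

  solved <- numeric(nrow(pairs))
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      pa <- pairs$pos_a[k]; pb <- pairs$pos_b[k]; d <- pairs$distance[k]
      ta <- res_tmpl(pa); tb <- res_tmpl(pb)
      sa <- sidechain_xyz(ta); sb <- sidechain_xyz(tb)
      if (nrow(sa) == 0L || nrow(sb) == 0L) {
        stop("infeasible geometry: planted pair ", pa, "-", pb,
             " involves a residue without sidechain heavy atoms")
      }
      island <- c(60 * k, 0, 0)
      ## pre-align one sidechain atom of each partner, then pull the second
      ## residue away along y until the minimum distance hits the target
      shift <- as.numeric(sa[1L, ] - sb[1L, ])
      f <- function(t) {
        min_pair_dist(sa, sweep(sb, 2L, shift + c(0, t, 0), "+")) - d
      }
      t_star <- stats::uniroot(f, c(0, d + 40), tol = 1e-9)$root
      ## land a hair inside the requested distance so that a pair planted
      ## exactly at a cutoff is detected under the inclusive boundary
      t_star <- max(t_star - 1e-6, 0)
      off_b <- shift + c(0, t_star, 0)
      solved[k] <- min_pair_dist(sa, sweep(sb, 2L, off_b, "+"))
      if (pairs$relation[k] == "intra") {
        for (ch in chains) {
          put(pa, ta, island + chain_off[[ch]], ch)
          put(pb, tb, island + off_b + chain_off[[ch]], ch)
        }
      } else {
        for (ch in chains) put(pa, ta, island + chain_off[[ch]], ch)
        ## partner copies: adjacent-chain copy sits next to chain A's residue
        put(pb, tb, island + off_b, "B")
        for (ch in c("A", "C", "D")) {
          put(pb, tb, island + c(0, 40, 0) + chain_off[[ch]], ch)
        }
      }
    }
  }
  for (j in seq_along(extra_positions)) {
    pos <- extra_positions[j]
    tmpl <- res_tmpl(pos)
    island <- c(60 * (nrow(pairs) + j), 0, 0)
    for (ch in chains) put(pos, tmpl, island + chain_off[[ch]], ch)
  }

  at <- do.call(rbind, atoms)
  at <- at[order(at$chain, at$resno), , drop = FALSE]
  rownames(at) <- NULL
  model <- new_structure_model(at)

  if (!is.null(file)) write_structure(model, file)
  gt <- pairs
  gt$realized <- solved
  list(model = model, ground_truth = gt, file = file)
}

#' Run the whole synthetic study
#'
#' Orchestrates the four generators coherently: the alignment fixes the
#' sequences; variant tables place reference VUSs on the planted transfer
#' positions and on the structural contact positions; the score table
#' forces the contact positions into the pathogenic component of the gate
#' tool's mixture (contacts are sought between high-scoring candidates);
#' the structure realizes the planted contact layout with the reference
#' residue types. Identical seed and configuration give byte-identical
#' artifacts.
#'
#' @param config A `sim_config`.
#' @return List with `config`, `tables`, `catalog`, `scores`, `alignment`,
#'   `paralogue_lpp`, `transfer_positions`, `structure` (model +
#'   ground truth), `segmap`, and `planted` summary counts.
#' @export
simulate_study <- function(config = sim_config()) {
  aln <- gen_alignment(config)

  ## structural contact positions: drawn per segment, avoiding transfer
  ## positions and glycines (no sidechain heavy atoms)
  sim_substream(config$seed, 4L)
  segmap <- config$segmap
  layout <- config$contact_layout
  need <- table(c(rep(layout$seg_a, layout$n), rep(layout$seg_b, layout$n)))
  pool <- list()
  for (seg in names(need)) {
    rng <- segmap[segmap$name == seg, ]
    if (nrow(rng) == 0L) stop("contact layout references unknown segment: ", seg)
    cand <- setdiff(seq(rng$start, rng$end), aln$transfer_positions)
    cand <- cand[aln$ref_seq[cand] != "G" & cand <= config$seq_length]
    if (length(cand) < need[[seg]]) stop("segment ", seg, " too small for layout")
    pool[[seg]] <- sample(cand, need[[seg]])
  }
  used <- stats::setNames(rep(0L, length(pool)), names(pool))
  pair_rows <- list()
  for (i in seq_len(nrow(layout))) {
    for (j in seq_len(layout$n[i])) {
      a <- pool[[layout$seg_a[i]]][used[[layout$seg_a[i]]] + 1L]
      used[[layout$seg_a[i]]] <- used[[layout$seg_a[i]]] + 1L
      b <- pool[[layout$seg_b[i]]][used[[layout$seg_b[i]]] + 1L]
      used[[layout$seg_b[i]]] <- used[[layout$seg_b[i]]] + 1L
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        pos_a = a, pos_b = b,
        distance = stats::runif(1, layout$d_lo[i], layout$d_hi[i]),
        relation = layout$relation[i], stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pair_rows)
  contact_positions <- sort(unique(c(pairs$pos_a, pairs$pos_b)))

  ## reference VUS placement: transfer positions (with doubles) + one VUS
  ## per contact position; one benign variant on a transfer position
  tp <- aln$transfer_positions
  benign_at <- tp[1L]
  vus_tp <- tp[-1L]
  extra <- config$n_ref_vus_at_transfers - length(vus_tp)
  vus_positions <- c(vus_tp, if (extra > 0) vus_tp[seq_len(extra)])
  ref_vus <- c(vus_positions, contact_positions)

  tables <- gen_variant_tables(config, alignment = aln,
                               ref_vus_positions = ref_vus,
                               ref_benign_positions = benign_at)
  catalog <- assemble_catalog(tables)
  scores <- gen_scores(config, catalog,
                       forced_pathogenic_positions = contact_positions)

  residues <- stats::setNames(aln$ref_seq[contact_positions],
                              contact_positions)
  struct <- gen_structure(pairs, residues)

  planted <- list(
    n_lpp = sum(config$genes$n_lpp), n_vus = sum(config$genes$n_vus),
    n_benign = sum(config$genes$n_benign),
    n_transfers = sum(aln$paralogue_lpp$transferable),
    n_transfer_positions = length(unique(
      aln$paralogue_lpp$expected_ref_position[aln$paralogue_lpp$transferable])),
    n_contact_pairs_in_cutoff = sum(pairs$distance <= 5.0))

  list(config = config, tables = tables, catalog = catalog, scores = scores,
       alignment = aln$alignment, paralogue_lpp = aln$paralogue_lpp,
       transfer_positions = aln$transfer_positions, structure = struct,
       segmap = segmap, planted = planted)
}

#' Write all synthetic fixtures to a directory
#'
#' Formats are identical to the real-input formats of the analysis
#' modules: per-source variant TSVs, a score TSV, aligned FASTA, a PDB
#' file and the segment-map YAML.
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (src in names(sim$tables)) {
    p <- file.path(dir, paste0("variants_", src, ".tsv"))
    utils::write.table(sim$tables[[src]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, p)
  }
  sp <- file.path(dir, "scores.tsv")
  write_score_table(sim$scores, sp)
  ap <- file.path(dir, "alignment.fasta")
  write_alignment(sim$alignment, ap)
  pp <- file.path(dir, "structure.pdb")
  write_structure(sim$structure$model, pp)
  invisible(c(files, sp, ap, pp))
}
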