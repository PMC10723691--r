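# Shared fixtures built in code: a hand-classified multi-source variant
# fixture, a small simulation configuration, and brute-force oracles used
# to cross-check AUC, transfers and contact detection.

# Three-source fixture with hand-assigned expected classes:
# 5 LPP, 3 BENIGN, 4 VUS, 1 CIP, 2 EXCLUDED.
variant_fixture_tables <- function() {
  row <- function(source, gene, label, sig, cond = "", af = NA_real_) {
    data.frame(gene = gene, accession = paste0("ACC_", gene),
               protein_change = label, clinical_significance = sig,
               condition = cond, allele_frequency = af, source = source,
               stringsAsFactors = FALSE)
  }
  list(
    humsavar = rbind(
      row("humsavar", "GENE1", "A10V", "Likely pathogenic"),       # LPP
      row("humsavar", "GENE1", "L40P", "Likely pathogenic"),       # LPP (also ensembl)
      row("humsavar", "GENE1", "H80Y", "Likely pathogenic")),      # vetoed -> VUS
    ensembl = rbind(
      row("ensembl", "GENE1", "R20W", "Pathogenic"),               # LPP
      row("ensembl", "GENE1", "L40P", "Likely pathogenic")),       # dup of humsavar row
    clinvar = rbind(
      row("clinvar", "GENE1", "K30E", "Pathogenic",
          cond = "Progressive familial heart block type IB"),      # LPP
      row("clinvar", "GENE2", "C15Y", "Likely pathogenic",
          cond = "Brugada syndrome"),                              # LPP
      row("clinvar", "GENE1", "G70S", "Uncertain significance"),   # VUS
      row("clinvar", "GENE1", "H80Y", "Uncertain significance"),   # VUS (veto case)
      row("clinvar", "GENE2", "I35T", "Uncertain significance"),   # VUS
      row("clinvar", "GENE2", "M45R", "Uncertain significance"),   # VUS
      row("clinvar", "GENE2", "T55I",
          "Conflicting interpretations of pathogenicity"),         # CIP
      row("clinvar", "GENE1", "S95T", "Pathogenic")),              # no condition -> EXCLUDED
    gnomad = rbind(
      row("gnomad", "GENE1", "D50N", "", af = 1e-4),               # BENIGN
      row("gnomad", "GENE1", "E60K", "", af = 2e-4),               # BENIGN
      row("gnomad", "GENE2", "F25L", "", af = 6e-5),               # BENIGN
      row("gnomad", "GENE1", "P90L", "", af = 5e-5)))              # at threshold -> EXCLUDED
}

# Scaled-down simulation for fast integration tests: 3 genes, short
# sequences, 6 transferable paralogue variants on 4 positions, 6 planted
# structural pairs.
small_segmap <- function() {
  vustriage:::as_segment_map(data.frame(
    name = c("S1", "S4", "MHR1/2", "MHR3"),
    start = c(1L, 41L, 81L, 161L),
    end = c(40L, 80L, 160L, 240L),
    region = c("transmembrane_extracellular", "transmembrane_extracellular",
               "cytoplasmic", "cytoplasmic"),
    stringsAsFactors = FALSE))
}

small_sim_config <- function(seed = 7) {
  genes <- data.frame(
    gene = c("REFG", "PARA", "PARB"),
    accession = c("Q00001", "Q00002", "Q00003"),
    n_lpp = c(2L, 8L, 6L), n_vus = c(40L, 5L, 5L), n_benign = c(3L, 4L, 3L),
    stringsAsFactors = FALSE)
  layout <- rbind(
    data.frame(seg_a = "S1", seg_b = "S4", relation = "intra", n = 2,
               d_lo = 3.6, d_hi = 4.9),
    data.frame(seg_a = "MHR1/2", seg_b = "MHR3", relation = "intra", n = 2,
               d_lo = 3.6, d_hi = 4.9),
    data.frame(seg_a = "S1", seg_b = "S4", relation = "inter", n = 1,
               d_lo = 3.6, d_hi = 4.9),
    data.frame(seg_a = "S1", seg_b = "S4", relation = "intra", n = 1,
               d_lo = 5.5, d_hi = 8.0))
  sim_config(seed = seed, genes = genes, reference_gene = "REFG",
             seq_length = 300, n_transfer_variants = 6,
             n_transfer_positions = 4, n_unmapped_lpp = 2,
             n_ref_vus_at_transfers = 5, contact_layout = layout,
             segmap = small_segmap())
}

# Minimal labelled catalog for score-generator tests.
fake_catalog <- function(n_pos, n_neg, gene = "G1") {
  n <- n_pos + n_neg
  df <- data.frame(
    gene = gene, accession = "Q0", position = seq_len(n),
    ref_aa = "A", alt_aa = "V",
    label = paste0("A", seq_len(n), "V"),
    class = c(rep("LPP", n_pos), rep("BENIGN", n_neg)),
    af = NA_real_, sources = "clinvar", conditions = "", flag = "",
    stringsAsFactors = FALSE)
  vustriage:::as_variant_catalog(df)
}

# Exhaustive positive x negative pair-counting AUC oracle (ties half).
auc_oracle <- function(scores, labels, direction = "damaging_if_greater") {
  keep <- !is.na(scores)
  s <- scores[keep]; l <- labels[keep]
  if (direction == "damaging_if_less") s <- -s
  pos <- s[l == "LPP"]; neg <- s[l == "BENIGN"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Brute-force transfer oracle: double loop over paralogue LPP variants and
# alignment columns.
transfer_oracle <- function(catalog, alignment, cs_threshold = 0.3) {
  ref <- alignment$reference_id
  lpp <- catalog[catalog$class == "LPP" & catalog$gene != ref &
                   catalog$gene %in% names(alignment$sequences), , drop = FALSE]
  hits <- list()
  for (i in seq_len(nrow(lpp))) {
    g <- lpp$gene[i]
    row <- strsplit(alignment$sequences[[g]], "")[[1]]
    refrow <- strsplit(alignment$sequences[[ref]], "")[[1]]
    p <- 0L
    for (col in seq_along(row)) {
      if (row[col] == "-") next
      p <- p + 1L
      if (p != lpp$position[i]) next
      if (refrow[col] == "-") break
      cs <- conservation_score(vapply(names(alignment$sequences),
                                      function(id) substr(alignment$sequences[[id]], col, col), ""))
      if (cs > cs_threshold) {
        hits[[length(hits) + 1L]] <- data.frame(
          paralogue = g, paralogue_variant = lpp$label[i],
          ref_position = sum(refrow[seq_len(col)] != "-"),
          stringsAsFactors = FALSE)
      }
      break
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) data.frame(paralogue = character(), paralogue_variant = character(),
                               ref_position = integer()) else out
}

# Brute-force all-atom-pair contact oracle.
contact_oracle <- function(model, positions, segmap, cutoff) {
  at <- model$atoms
  sc <- at[at$resno %in% positions &
             !(at$elety %in% c("N", "CA", "C", "O", "OXT")) &
             !grepl("^[0-9]*H", at$elety), , drop = FALSE]
  n <- nrow(sc)
  x <- sc$x; y <- sc$y; z <- sc$z; rn <- sc$resno; ch <- sc$chain
  best <- list()
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (rn[i] == rn[j] && ch[i] == ch[j]) next
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2 + (z[i] - z[j])^2)
    if (d > cutoff) next
    pa <- min(rn[i], rn[j]); pb <- max(rn[i], rn[j])
    rel <- if (ch[i] == ch[j]) "intra" else "inter"
    if (pa == pb && rel == "intra") next
    sa <- segment_of(segmap, pa); sb <- segment_of(segmap, pb)
    if (is.na(sa) || is.na(sb)) next
    if (sa == sb && rel == "intra") next
    key <- paste(pa, pb, rel)
    if (is.null(best[[key]]) || d < best[[key]]$distance) {
      best[[key]] <- data.frame(pos_a = pa, pos_b = pb, relation = rel,
                                distance = d, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, unname(best))
  if (is.null(out)) {
    return(data.frame(pos_a = integer(), pos_b = integer(),
                      relation = character(), distance = numeric()))
  }
  out <- out[order(out$pos_a, out$pos_b, out$relation), ]
  rownames(out) <- NULL
  out
}

contact_key <- function(df) sort(paste(df$pos_a, df$pos_b, df$relation))

# Toy structure shared by several structure tests: 6 planted pairs across
# segments plus one isolated glycine.
toy_structure <- function(seed = 11) {
  set.seed(seed)
  pairs <- data.frame(
    pos_a = c(5L, 10L, 50L, 90L, 95L, 20L),
    pos_b = c(45L, 55L, 100L, 170L, 175L, 60L),
    distance = c(4.9, 4.2, 3.8, 4.5, 5.1, 6.5),
    relation = c("intra", "intra", "inter", "intra", "intra", "intra"),
    stringsAsFactors = FALSE)
  residues <- setNames(
    c("R", "L", "D", "K", "Y", "V", "S", "F", "T", "N", "W", "E", "G"),
    c(5, 10, 20, 45, 50, 55, 60, 90, 95, 100, 170, 175, 150))
  gen_structure(pairs, residues, extra_positions = 150L)
}
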