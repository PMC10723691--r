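test_that("generated tables assemble into exactly the planted class counts", {
  cfg <- small_sim_config(seed = 37)
  sim <- simulate_study(cfg)
  counts <- table(sim$catalog$class)
  expect_equal(unname(counts["LPP"]), sum(cfg$genes$n_lpp))
  expect_equal(unname(counts["VUS"]), sum(cfg$genes$n_vus))
  expect_equal(unname(counts["BENIGN"]), sum(cfg$genes$n_benign))
  # benign AFs strictly above the threshold
  expect_true(all(sim$catalog$af[sim$catalog$class == "BENIGN"] > 5e-5))
  # the planted Humsavar-LP/ClinVar-VUS conflict stays VUS
  veto <- sim$catalog[grepl("humsavar", sim$catalog$sources) &
                        grepl("clinvar", sim$catalog$sources) &
                        sim$catalog$gene == "REFG", ]
  expect_gte(nrow(veto), 1L)
  expect_true(all(veto$class == "VUS"))
})

test_that("zero-count configs produce an empty catalog", {
  genes <- data.frame(gene = c("REFG", "PARA"), accession = c("Q1", "Q2"),
                      n_lpp = 0L, n_vus = 0L, n_benign = 0L,
                      stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 1, genes = genes, reference_gene = "REFG",
                    seq_length = 300, n_transfer_variants = 0,
                    n_transfer_positions = 0, n_unmapped_lpp = 0,
                    n_ref_vus_at_transfers = 0, n_veto = 0,
                    segmap = small_segmap(),
                    contact_layout = default_contact_layout()[0, ])
  tabs <- gen_variant_tables(cfg)
  expect_equal(nrow(assemble_catalog(tabs)), 0L)
})

test_that("score separation matches the analytic concordance target", {
  n <- 2000L
  cat2k <- fake_catalog(n, n)
  for (target in c(0.5, 0.90)) {
    tools <- data.frame(tool = "T1", auc = target,
                        direction = "damaging_if_greater", threshold = 0.5,
                        lo = 0, hi = 1, missing = 0)
    cfg <- sim_config(seed = 41, genes = data.frame(
      gene = "G1", accession = "Q0", n_lpp = n, n_vus = 0L, n_benign = n),
      reference_gene = "G1", tools = tools, segmap = small_segmap(),
      contact_layout = default_contact_layout()[0, ])
    sc <- gen_scores(cfg, cat2k)
    emp <- roc_curve(sc$T1, cat2k$class)$auc
    # Hanley-McNeil standard error at the target value
    q1 <- target / (2 - target); q2 <- 2 * target^2 / (1 + target)
    se <- sqrt((target * (1 - target) + (n - 1) * (q1 - target^2) +
                  (n - 1) * (q2 - target^2)) / (n * n))
    expect_lt(abs(emp - target), 3 * max(se, 1e-3))
  }
})

test_that("a near-perfect separation target yields near-perfect AUC", {
  cat500 <- fake_catalog(500, 500)
  tools <- data.frame(tool = "T1", auc = 1, direction = "damaging_if_greater",
                      threshold = 0.5, lo = 0, hi = 1, missing = 0)
  cfg <- sim_config(seed = 43, genes = data.frame(
    gene = "G1", accession = "Q0", n_lpp = 500L, n_vus = 0L, n_benign = 500L),
    reference_gene = "G1", tools = tools, segmap = small_segmap(),
    contact_layout = default_contact_layout()[0, ])
  sc <- gen_scores(cfg, cat500)
  expect_gte(roc_curve(sc$T1, cat500$class)$auc, 0.999)
})

test_that("configured missingness appears in the score table", {
  cat100 <- fake_catalog(50, 50)
  tools <- data.frame(tool = "T1", auc = 0.8, direction = "damaging_if_greater",
                      threshold = 0.5, lo = 0, hi = 1, missing = 0.75)
  cfg <- sim_config(seed = 47, genes = data.frame(
    gene = "G1", accession = "Q0", n_lpp = 50L, n_vus = 0L, n_benign = 50L),
    reference_gene = "G1", tools = tools, segmap = small_segmap(),
    contact_layout = default_contact_layout()[0, ])
  sc <- gen_scores(cfg, cat100)
  expect_gt(mean(is.na(sc$T1)), 0.5)
  expect_equal(coverage_filter(sc, 0.30), character(0))
})

test_that("alignment generator plants conserved and divergent columns", {
  cfg <- small_sim_config(seed = 53)
  aln <- vustriage:::gen_alignment(cfg)
  track <- conservation_track(aln$alignment)
  # transferable planted positions sit in fully conserved columns
  cols <- track$column[match(aln$transfer_positions, track$ref_position)]
  expect_true(all(track$cs[cols] == 1))
  # non-transferable planted variants sit below the gate (or unmapped)
  nt <- aln$paralogue_lpp[!aln$paralogue_lpp$transferable, ]
  for (i in seq_len(nrow(nt))) {
    col <- vustriage:::residue_column(aln$alignment, nt$gene[i], nt$position[i])
    refpos <- vustriage:::column_position(aln$alignment,
                                          aln$alignment$reference_id, col)
    expect_true(is.na(refpos) || track$cs[col] <= 0.3)
  }
})

test_that("identical seeds give byte-identical fixtures, different seeds differ", {
  cfg <- small_sim_config(seed = 59)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  write_simulation(simulate_study(cfg), d1)
  write_simulation(simulate_study(small_sim_config(seed = 59)), d2)
  write_simulation(simulate_study(small_sim_config(seed = 60)), d3)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_false(identical(readLines(file.path(d1, "scores.tsv")),
                         readLines(file.path(d3, "scores.tsv"))))
})

test_that("score table TSV round-trips", {
  sim <- simulate_study(small_sim_config(seed = 61))
  tmp <- tempfile(fileext = ".tsv")
  write_score_table(sim$scores, tmp)
  back <- read_score_table(tmp)
  expect_equal(back$ClinPred, sim$scores$ClinPred)
  expect_identical(back$variant_id, sim$scores$variant_id)
})
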