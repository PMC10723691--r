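## Consensus calls and report bundle: combine the predictor gate, paralogue
## transfers and structural contact evidence into tiered candidate lists.

#' Gate VUS records on a predictor score
#'
#' Selects the reference-gene VUS records whose score from `gate_tool`
#' strictly exceeds `gate` (for a greater-is-damaging tool; reversed
#' otherwise).
#'
#' @param catalog A `variant_catalog`.
#' @param scores Score table (`variant_id` + tool columns).
#' @param gene Reference gene symbol.
#' @param gate_tool Tool used as the gate (default `"ClinPred"`).
#' @param gate Score threshold (default 0.6, strict).
#' @param direction Score orientation of the gate tool.
#' @return Data.frame of gated VUS rows with an added `score` column.
#' @export
gate_vus <- function(catalog, scores, gene, gate_tool = "ClinPred", gate = 0.6,
                     direction = "damaging_if_greater") {
  vus <- as.data.frame(catalog)[catalog$class == "VUS" & catalog$gene == gene, ,
                                drop = FALSE]
  s <- scores[[gate_tool]][match(variant_id(vus), scores$variant_id)]
  vus$score <- s
  keep <- !is.na(s) & if (direction == "damaging_if_greater") s > gate else s < gate
  out <- vus[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus LP/P calls from predictor gate and paralogue transfers
#'
#' The consensus tier contains the gated VUSs whose position received at
#' least one paralogue LP/P transfer (conservation-gated). Both inputs must
#' derive from the same catalog.
#'
#' @param gated Gated VUS data.frame from [gate_vus()].
#' @param transfers A `paralogue_transfers` object.
#' @return Data.frame of calls with `tier = "consensus_LPP"` and the
#'   supporting paralogue variants attached.
#' @export
consensus_lpp <- function(gated, transfers) {
  hit <- gated$position %in% transfers$ref_position
  calls <- gated[hit, , drop = FALSE]
  support <- vapply(calls$position, function(p) {
    tr <- transfers[transfers$ref_position == p, ]
    paste(paste0(tr$paralogue, ":", tr$paralogue_variant), collapse = ",")
  }, "")
  calls$tier <- rep("consensus_LPP", nrow(calls))
  calls$support <- support
  rownames(calls) <- NULL
  calls
}

#' Contact-implicated calls
#'
#' Every gated VUS whose parental (wild-type) residue participates in at
#' least one detected contact is implicated; the partner position(s) are
#' attached as support.
#'
#' @param gated Gated VUS data.frame from [gate_vus()].
#' @param contacts A `contact_set` (computed over the gated selection).
#' @return Data.frame of calls with `tier = "contact_implicated"`.
#' @export
contact_implicated <- function(gated, contacts) {
  pos_in_contact <- unique(c(contacts$pos_a, contacts$pos_b))
  calls <- gated[gated$position %in% pos_in_contact, , drop = FALSE]
  support <- vapply(calls$position, function(p) {
    partners <- sort(unique(c(contacts$pos_b[contacts$pos_a == p],
                              contacts$pos_a[contacts$pos_b == p])))
    paste(partners, collapse = ",")
  }, "")
  calls$tier <- rep("contact_implicated", nrow(calls))
  calls$support <- support
  rownames(calls) <- NULL
  calls
}

#' Run the full triage pipeline
#'
#' Executes benchmark, predictor gating, paralogue transfer, contact
#' detection and consensus tiering on one catalog, and collects headline
#' counts. Candidate totals are reported both as the per-analysis sum
#' (which can double-count variants supported by several lines of
#' evidence) and as the distinct-variant union.
#'
#' @param catalog A `variant_catalog`.
#' @param scores Score table.
#' @param alignment A `paralogue_alignment` (reference id = reference gene).
#' @param model A `structure_model` of the reference channel tetramer.
#' @param segmap A `segment_map`.
#' @param tool_config Tool configuration ([read_tool_config()]).
#' @param gate_tool,gate Predictor gate (default ClinPred, score > 0.6).
#' @param cs_threshold Conservation gate for transfers (default 0.3).
#' @param cutoff Contact cutoff in Angstrom (default 5.0).
#' @param min_coverage Benchmark coverage filter (default 0.30).
#' @return A `triage_result` list: `catalog`, `benchmark`, `gated`,
#'   `transfers`, `contacts`, `contacts_by_region`, `calls`, `summary`.
#' @export
run_triage <- function(catalog, scores, alignment, model, segmap,
                       tool_config = read_tool_config(),
                       gate_tool = "ClinPred", gate = 0.6,
                       cs_threshold = 0.3, cutoff = 5.0, min_coverage = 0.30) {
  ref_gene <- alignment$reference_id
  bench <- benchmark_predictors(catalog, scores, tool_config, min_coverage)
  gated <- gate_vus(catalog, scores, ref_gene, gate_tool, gate,
                    tool_config[[gate_tool]]$direction)
  transfers <- transfer_lpp(catalog, alignment, cs_threshold)
  selection <- data.frame(position = gated$position, variant = gated$label,
                          score = gated$score, stringsAsFactors = FALSE)
  contacts <- suppressWarnings(
    detect_contacts(model, selection, segmap, cutoff))
  by_region <- partition_by_region(contacts, segmap)

  cons <- consensus_lpp(gated, transfers)
  impl <- contact_implicated(gated, contacts)
  pred_only <- gated[!(variant_id(gated) %in%
                         c(variant_id(cons), variant_id(impl))), , drop = FALSE]
  if (nrow(pred_only)) {
    pred_only$tier <- "predictor_only"
    pred_only$support <- ""
  } else {
    pred_only$tier <- character(0)
    pred_only$support <- character(0)
  }
  calls <- rbind(cons, impl, pred_only)
  tier_rank <- c(consensus_LPP = 1L, contact_implicated = 2L, predictor_only = 3L)
  calls <- calls[order(tier_rank[calls$tier], calls$position, calls$alt_aa), ]
  rownames(calls) <- NULL

  impl_tm <- contact_implicated(gated, by_region$transmembrane_extracellular)
  impl_cyto <- contact_implicated(gated, by_region$cytoplasmic)
  summary <- list(
    n_variants = nrow(catalog),
    n_lpp = sum(catalog$class == "LPP"),
    n_benign = sum(catalog$class == "BENIGN"),
    n_vus = sum(catalog$class == "VUS"),
    n_vus_reference = sum(catalog$class == "VUS" & catalog$gene == ref_gene),
    n_gated_vus = nrow(gated),
    n_transfers = nrow(transfers),
    n_transfer_positions = length(unique(transfers$ref_position)),
    n_consensus_lpp = nrow(cons),
    n_contacts_tm = nrow(by_region$transmembrane_extracellular),
    n_contacts_cyto = nrow(by_region$cytoplasmic),
    n_vus_tm_contacts = nrow(impl_tm),
    n_residues_cyto_contacts = length(unique(c(
      by_region$cytoplasmic$pos_a, by_region$cytoplasmic$pos_b))),
    n_vus_cyto_contacts = nrow(impl_cyto),
    n_contact_implicated = nrow(impl),
    n_candidates_sum = nrow(cons) + nrow(impl),
    n_candidates_distinct = length(unique(variant_id(rbind(cons, impl)))))

  structure(list(catalog = catalog, benchmark = bench, gated = gated,
                 transfers = transfers, contacts = contacts,
                 contacts_by_region = by_region, calls = calls,
                 summary = summary),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  s <- x$summary
  cat("Variant triage result\n",
      "  catalog: ", s$n_variants, " variants (", s$n_lpp, " LP/P, ",
      s$n_benign, " benign, ", s$n_vus, " VUS; reference gene VUS: ",
      s$n_vus_reference, ")\n",
      "  predictor gate:       ", s$n_gated_vus, " high-score VUS\n",
      "  paralogue transfers:  ", s$n_transfers, " onto ",
      s$n_transfer_positions, " positions -> ", s$n_consensus_lpp,
      " consensus LP/P calls\n",
      "  contacts:             ", s$n_contacts_tm, " TM/extracellular + ",
      s$n_contacts_cyto, " cytoplasmic -> ", s$n_contact_implicated,
      " contact-implicated VUS\n",
      "  candidates:           ", s$n_candidates_sum, " (per-analysis sum), ",
      s$n_candidates_distinct, " distinct\n", sep = "")
  invisible(x)
}

#' Write the report bundle
#'
#' Emits the catalog, per-gene counts, predictor performance, transfer,
#' contact and consensus tables as TSV plus a JSON summary of all headline
#' counts. Output is deterministic (fixed ordering, no timestamps):
#' regenerating from identical inputs is byte-identical. All stages must
#' have been computed from the same catalog; mismatched provenance is an
#' error.
#'
#' @param result A `triage_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
build_report <- function(result, dir) {
  stopifnot(inherits(result, "triage_result"))
  h <- attr(result$catalog, "catalog_hash")
  for (stage in list(result$benchmark, result$transfers)) {
    hs <- attr(stage, "catalog_hash")
    if (!is.null(hs) && !identical(hs, h)) {
      stop("stage provenance mismatch: not all results derive from this catalog")
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(as.data.frame(df), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }
  files <- c(
    tsv(result$catalog, "catalog.tsv"),
    tsv(catalog_counts(result$catalog), "catalog_counts.tsv"),
    tsv(result$benchmark, "performance.tsv"),
    tsv(result$transfers, "transfers.tsv"),
    tsv(result$contacts_by_region$transmembrane_extracellular,
        "contacts_transmembrane.tsv"),
    tsv(result$contacts_by_region$cytoplasmic, "contacts_cytoplasmic.tsv"),
    tsv(result$calls, "consensus_calls.tsv"))
  sp <- file.path(dir, "summary.json")
  jsonlite::write_json(result$summary, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, sp))
}
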