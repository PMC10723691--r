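## Structure contacts: parse a (homotetrameric) channel structure, select
## sidechain heavy atoms, detect intersegment contacts between candidate
## positions and classify them by topology segment pair.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Read a channel structure
#'
#' Parses PDB or mmCIF coordinates (via bio3d), keeps ATOM records, and
#' resolves alternate locations by retaining the highest-occupancy
#' conformer per atom (ties prefer altloc `A`). Author residue numbering is
#' kept as-is; for the reference channel it is expected to match UniProt
#' positions.
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @return A `structure_model`: list with `atoms` (data.frame `chain`,
#'   `resno`, `resid`, `elety`, `x`, `y`, `z`, `o`) and `chains`.
#' @export
read_structure <- function(path) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  }
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  at$o[is.na(at$o)] <- 1
  at$alt[is.na(at$alt)] <- ""
  key <- paste(at$chain, at$resno, at$elety, sep = "|")
  ## highest occupancy per atom; ties -> altloc 'A' (then file order)
  ord <- order(key, -at$o, at$alt != "A", at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety, sep = "|")), , drop = FALSE]
  atoms <- data.frame(chain = at$chain, resno = as.integer(at$resno),
                      resid = at$resid, elety = at$elety,
                      x = at$x, y = at$y, z = at$z, o = at$o,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", path)
  }
  new_structure_model(atoms)
}

new_structure_model <- function(atoms) {
  structure(list(atoms = atoms, chains = sort(unique(atoms$chain))),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,", length(x$chains), "chain(s) [",
      paste(x$chains, collapse = " "), "],",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues\n")
  invisible(x)
}

#' Write a structure model as PDB
#' @param model A `structure_model`.
#' @param path Output file.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   o = at$o, b = rep(0, nrow(at)))
  invisible(path)
}

is_hydrogen <- function(elety) grepl("^[0-9]*H", elety)

#' Sidechain heavy atoms of a residue
#'
#' All atoms except the backbone (N, CA, C, O, OXT) and hydrogens. Glycine
#' yields an empty set; alanine exactly CB. A residue whose sidechain is
#' unresolved in the model yields an empty set with a warning.
#'
#' @param model A `structure_model`.
#' @param chain Chain id.
#' @param resno Author residue number.
#' @return Data.frame of atom rows (possibly empty).
#' @export
sidechain_heavy_atoms <- function(model, chain, resno) {
  at <- model$atoms
  res <- at[at$chain == chain & at$resno == resno, , drop = FALSE]
  if (nrow(res) == 0L) stop("residue ", chain, ":", resno, " not in structure")
  sc <- res[!(res$elety %in% BACKBONE_ATOMS) & !is_hydrogen(res$elety), , drop = FALSE]
  if (nrow(sc) == 0L && !all(res$resid %in% "GLY")) {
    warning("sidechain of ", res$resid[1L], " ", chain, ":", resno,
            " is unresolved")
  }
  sc
}

#' Read a topology segment map
#'
#' YAML with a `segments` list of `{name, start, end, region}` entries;
#' `region` is `transmembrane_extracellular` or `cytoplasmic`. Ranges must
#' not overlap. The TRPM4-curated map shipped with the package is at
#' `system.file("extdata", "trpm4_segments.yaml", package = "vustriage")`.
#'
#' @param path YAML file; defaults to the shipped TRPM4 map.
#' @return A `segment_map` data.frame (`name`, `start`, `end`, `region`).
#' @export
read_segment_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "trpm4_segments.yaml", package = "vustriage")
  }
  raw <- yaml::read_yaml(path)$segments
  df <- do.call(rbind, lapply(raw, function(s) {
    data.frame(name = s$name, start = as.integer(s$start),
               end = as.integer(s$end), region = s$region,
               stringsAsFactors = FALSE)
  }))
  as_segment_map(df)
}

as_segment_map <- function(df) {
  stopifnot(all(df$region %in% c("transmembrane_extracellular", "cytoplasmic")),
            all(df$start <= df$end))
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 1L && any(df$start[-1L] <= df$end[-nrow(df)])) {
    stop("segment ranges overlap")
  }
  rownames(df) <- NULL
  class(df) <- c("segment_map", "data.frame")
  df
}

#' Segment and region lookup for residue positions
#' @param segmap A `segment_map`.
#' @param position Integer vector of residue positions.
#' @return Character vector of segment names (`NA` if unannotated).
#' @export
segment_of <- function(segmap, position) {
  idx <- vapply(position, function(p) {
    hit <- which(segmap$start <= p & segmap$end >= p)
    if (length(hit)) hit[1L] else NA_integer_
  }, 1L)
  segmap$name[idx]
}

#' @rdname segment_of
#' @param name Segment name(s).
#' @export
region_of <- function(segmap, name) {
  segmap$region[match(name, segmap$name)]
}

## Minimum pairwise distance between two coordinate matrices (n x 3).
min_pair_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' Detect sidechain heavy-atom contacts between selected positions
#'
#' For every unordered pair of selected residue positions, over every chain
#' combination of the (tetrameric) model, the minimum distance between
#' sidechain heavy atoms is computed; pairs at or below `cutoff` that are
#' intersegment (different segments, or any segments on different chains)
#' are reported. Symmetric copies across subunits are merged to one
#' canonical pair per subunit relation (`intra` within one chain, `inter`
#' across chains), keeping the smallest distance and the chain pair that
#' attains it. Selected positions absent from the structure or from the
#' segment map are skipped with a warning. Glycine positions have no
#' sidechain heavy atoms and can never form contacts.
#'
#' @param model A `structure_model`.
#' @param selection Integer vector of residue positions, or a data.frame
#'   with columns `position` and optionally `variant` (supporting VUS
#'   labels, comma-joined per position) and `score`.
#' @param segmap A `segment_map`.
#' @param cutoff Contact cutoff in Angstrom (default 5.0, inclusive).
#' @param rules Contact-category rule table passed to [classify_contact()].
#' @return A `contact_set` data.frame: `pos_a`, `segment_a`, `chain_a`,
#'   `pos_b`, `segment_b`, `chain_b`, `distance`, `relation`, `category`,
#'   `vus_a`, `vus_b`, sorted by positions (`pos_a <= pos_b`).
#' @export
detect_contacts <- function(model, selection, segmap, cutoff = 5.0,
                            rules = default_contact_rules()) {
  stopifnot(cutoff > 0)
  if (is.data.frame(selection)) {
    sel_pos <- as.integer(selection$position)
    vus <- if (!is.null(selection$variant)) {
      tapply(selection$variant, selection$position,
             function(v) paste(sort(unique(v)), collapse = ","))
    } else NULL
  } else {
    sel_pos <- as.integer(selection)
    vus <- NULL
  }
  sel_pos <- sort(unique(sel_pos))
  if (length(sel_pos) == 0L) stop("empty selection")

  at <- model$atoms
  present <- sel_pos %in% at$resno
  if (any(!present)) {
    warning("selected position(s) absent from structure, skipped: ",
            paste(sel_pos[!present], collapse = ", "))
  }
  sel_pos <- sel_pos[present]
  seg <- segment_of(segmap, sel_pos)
  if (anyNA(seg)) {
    warning("selected position(s) outside segment map, skipped: ",
            paste(sel_pos[is.na(seg)], collapse = ", "))
    sel_pos <- sel_pos[!is.na(seg)]
    seg <- seg[!is.na(seg)]
  }
  names(seg) <- sel_pos

  sc <- at[at$resno %in% sel_pos & !(at$elety %in% BACKBONE_ATOMS) &
             !is_hydrogen(at$elety), , drop = FALSE]
  groups <- split(sc, paste(sc$resno, sc$chain, sep = "|"))
  ginfo <- data.frame(
    resno = as.integer(vapply(groups, function(g) g$resno[1L], 1L)),
    chain = vapply(groups, function(g) g$chain[1L], ""),
    stringsAsFactors = FALSE)
  coords <- lapply(groups, function(g) as.matrix(g[c("x", "y", "z")]))
  cent <- t(vapply(coords, colMeans, numeric(3)))
  radius <- vapply(seq_along(coords), function(i) {
    sqrt(max(rowSums((coords[[i]] - rep(cent[i, ], each = nrow(coords[[i]])))^2)))
  }, 0)

  n <- length(groups)
  best <- list()
  if (n > 1L) {
    cd <- as.matrix(stats::dist(cent))
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (ginfo$resno[i] == ginfo$resno[j] && ginfo$chain[i] == ginfo$chain[j]) next
        if (cd[i, j] > cutoff + radius[i] + radius[j]) next
        d <- min_pair_dist(coords[[i]], coords[[j]])
        if (d > cutoff) next
        pa <- min(ginfo$resno[i], ginfo$resno[j])
        pb <- max(ginfo$resno[i], ginfo$resno[j])
        rel <- if (ginfo$chain[i] == ginfo$chain[j]) "intra" else "inter"
        if (pa == pb && rel == "intra") next
        sa <- unname(seg[as.character(pa)]); sb <- unname(seg[as.character(pb)])
        if (sa == sb && rel == "intra") next  # intrasegment, same subunit
        key <- paste(pa, pb, rel, sep = "|")
        if (is.null(best[[key]]) || d < best[[key]]$distance) {
          ii <- if (ginfo$resno[i] <= ginfo$resno[j]) i else j
          jj <- if (ginfo$resno[i] <= ginfo$resno[j]) j else i
          best[[key]] <- data.frame(
            pos_a = pa, segment_a = sa, chain_a = ginfo$chain[ii],
            pos_b = pb, segment_b = sb, chain_b = ginfo$chain[jj],
            distance = d, relation = rel, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, unname(best))
  if (is.null(res)) {
    res <- data.frame(pos_a = integer(), segment_a = character(),
                      chain_a = character(), pos_b = integer(),
                      segment_b = character(), chain_b = character(),
                      distance = numeric(), relation = character(),
                      stringsAsFactors = FALSE)
  }
  res$category <- classify_contact(res$segment_a, res$segment_b, res$relation, rules)
  res$vus_a <- if (!is.null(vus)) unname(vus[as.character(res$pos_a)]) else
    rep(NA_character_, nrow(res))
  res$vus_b <- if (!is.null(vus)) unname(vus[as.character(res$pos_b)]) else
    rep(NA_character_, nrow(res))
  res <- res[order(res$pos_a, res$pos_b, res$relation), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("contact_set", "data.frame")
  attr(res, "cutoff") <- cutoff
  res
}

#' @export
print.contact_set <- function(x, ...) {
  cat("Contacts:", nrow(x), "canonical pair(s) at cutoff",
      attr(x, "cutoff"), "A\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Default contact-category rule table
#'
#' Categories are keyed on the unordered segment pair and the subunit
#' relation: S4 against S1/S2/S3 within a subunit are voltage-sensor
#' activation contacts; S4 (or the S4-S5 linker) against S5 of the next
#' subunit carry the sensor-to-pore signal; S1 against S5 across subunits
#' clamp the sensor to the pore; S5 against P1 within a subunit supports
#' pore-module folding; P1 against P2 stabilizes P-loop folding; S5
#' against S6 within a subunit relates to activation gating. Anything else
#' is `unclassified`.
#'
#' @return Data.frame with `seg1`, `seg2`, `relation`, `category`.
#' @export
default_contact_rules <- function() {
  rules <- rbind(
    c("S1", "S4", "intra", "VSM activation"),
    c("S2", "S4", "intra", "VSM activation"),
    c("S3", "S4", "intra", "VSM activation"),
    c("S4", "S5", "inter", "VSM-PM signal"),
    c("S4-S5 linker", "S5", "inter", "VSM-PM signal"),
    c("S1", "S5", "inter", "VSM-PM clamp"),
    c("S5", "P1", "intra", "PM folding"),
    c("P1", "P2", "intra", "P-loop folding"),
    c("S5", "S6", "intra", "activation gating"))
  stats::setNames(as.data.frame(rules, stringsAsFactors = FALSE),
                  c("seg1", "seg2", "relation", "category"))
}

#' Classify contacts by segment pair and subunit relation
#'
#' @param segment_a,segment_b Segment names (order-free).
#' @param relation `"intra"` or `"inter"`.
#' @param rules Rule table (see [default_contact_rules()]).
#' @return Character vector of category labels.
#' @export
classify_contact <- function(segment_a, segment_b, relation,
                             rules = default_contact_rules()) {
  if (length(segment_a) == 0L) return(character())
  s1 <- pmin(segment_a, segment_b)
  s2 <- pmax(segment_a, segment_b)
  rk <- paste(pmin(rules$seg1, rules$seg2), pmax(rules$seg1, rules$seg2),
              rules$relation, sep = "|")
  hit <- match(paste(s1, s2, relation, sep = "|"), rk)
  ifelse(is.na(hit), "unclassified", rules$category[hit])
}

PORE_SEGMENTS <- c("S5", "S6", "P1", "P2")

#' Partition contacts into transmembrane/extracellular and cytoplasmic
#'
#' A contact is transmembrane/extracellular when both residues lie in
#' segments of that region and cytoplasmic when both are cytoplasmic. A
#' contact spanning the two regions is assigned cytoplasmic — except pairs
#' within the pore-forming segments (S5, S6, P1, P2), which are
#' transmembrane — and is flagged as region-spanning.
#'
#' @param contacts A `contact_set`.
#' @param segmap A `segment_map`.
#' @return List with elements `transmembrane_extracellular` and
#'   `cytoplasmic`, each a `contact_set` with an added `region_spanning`
#'   flag column.
#' @export
partition_by_region <- function(contacts, segmap) {
  if (nrow(contacts) == 0L) {
    empty <- contacts
    empty$region_spanning <- logical()
    return(list(transmembrane_extracellular = empty, cytoplasmic = empty))
  }
  ra <- region_of(segmap, contacts$segment_a)
  rb <- region_of(segmap, contacts$segment_b)
  spanning <- ra != rb
  tm <- (ra == "transmembrane_extracellular" & rb == "transmembrane_extracellular") |
    (contacts$segment_a %in% PORE_SEGMENTS & contacts$segment_b %in% PORE_SEGMENTS)
  contacts$region_spanning <- spanning
  list(transmembrane_extracellular = contacts[tm, , drop = FALSE],
       cytoplasmic = contacts[!tm, , drop = FALSE])
}
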