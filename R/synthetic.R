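#' Synthetic reference catalog
#'
#' Builds a mock domain reference hierarchy: `n_groups` homologous groups
#' (H-groups), each holding 1-5 member domains with lengths 40-300. The five
#' structural classes are assigned round-robin across H-groups, kingdoms
#' alternate between eukaryote and bacteria, and H-groups are nested
#' pairwise into X-groups.
#'
#' @param n_groups Number of H-groups (at least 1).
#' @param seed Integer seed; the same seed reproduces the catalog exactly.
#' @return A catalog data frame (see [read_catalog()] for columns).
#' @examples
#' cat5 <- make_reference_catalog(5, seed = 1)
#' table(cat5$class5[!duplicated(cat5$h_group)])
#' @export
make_reference_catalog <- function(n_groups, seed = 1L) {
  if (!is.numeric(n_groups) || n_groups < 1) stop("n_groups must be >= 1")
  n_groups <- as.integer(n_groups)
  withr::with_seed(as.integer(seed), {
    classes <- class5_levels()
    archs <- c("bundles", "barrels", "layers", "ribbons")
    rows <- lapply(seq_len(n_groups), function(g) {
      n_mem <- sample.int(5L, 1L)
      data.frame(
        domain_id = sprintf("d%04d%02d", g, seq_len(n_mem)),
        f_group = sprintf("H%04d.%d", g, seq_len(n_mem)),
        h_group = sprintf("H%04d", g),
        x_group = sprintf("X%03d", (g - 1L) %/% 2L + 1L),
        architecture = archs[(g - 1L) %% length(archs) + 1L],
        class5 = classes[(g - 1L) %% length(classes) + 1L],
        length = sample(40:300, n_mem, replace = TRUE),
        kingdom = if (g %% 2L == 1L) "eukaryote" else "bacteria",
        stringsAsFactors = FALSE)
    })
    catalog <- do.call(rbind, rows)
    validate_catalog(catalog)
    catalog
  })
}

#' Specification for one synthetic predicted model
#'
#' Describes a chain as an ordered list of blocks plus the PAE/pLDDT
#' distributions used to fill the confidence fields. Defaults place
#' within-domain PAE around 4 Angstrom, between-domain PAE around 20 and
#' disordered PAE around 28, with ordered residues near pLDDT 90 and
#' disordered residues near 50 -- a block-structured caricature of predicted
#' model confidence, sufficient for the parser's assumptions and
#' configurable where real data would differ.
#'
#' @param blocks Data frame with columns `kind` (one of `domain`, `linker`,
#'   `disordered_tail`, `simple_helix`), `length`, `group_id` (required for
#'   `domain` blocks), `geometry` (`helix_bundle`, `sheet_sandwich`,
#'   `mixed`; ignored for non-domain blocks) and optionally `scenario`
#'   (`assigned`, `unassigned`, `partial`; default `assigned`).
#' @param pae_within,pae_between,pae_disorder Length-2 numeric `(mean, sd)`
#'   of the PAE (Angstrom) for same-domain pairs, cross-block pairs, and
#'   pairs touching a disordered/linker residue.
#' @param plddt_ordered,plddt_disordered Length-2 `(mean, sd)` of pLDDT for
#'   ordered and disordered residues.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(blocks,
                           pae_within = c(4, 1),
                           pae_between = c(20, 3),
                           pae_disorder = c(28, 2),
                           plddt_ordered = c(90, 5),
                           plddt_disordered = c(50, 10),
                           seed = 1L) {
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  if (nrow(blocks) == 0L) stop("spec must contain at least one block")
  stopifnot(all(c("kind", "length") %in% names(blocks)))
  if (is.null(blocks$group_id)) blocks$group_id <- NA_character_
  if (is.null(blocks$geometry)) blocks$geometry <- "helix_bundle"
  if (is.null(blocks$scenario)) blocks$scenario <- "assigned"
  blocks$scenario[blocks$kind != "domain"] <- NA_character_
  stopifnot(all(blocks$kind %in% c("domain", "linker", "disordered_tail",
                                   "simple_helix")),
            all(blocks$length >= 1),
            all(is.na(blocks$scenario) |
                  blocks$scenario %in% c("assigned", "unassigned", "partial")))
  if (any(blocks$kind == "domain" & is.na(blocks$group_id)))
    stop("domain blocks must carry a group_id")
  stopifnot(pae_within[1] >= 0, pae_between[1] >= 0, pae_disorder[1] >= 0)
  structure(list(blocks = blocks, pae_within = pae_within,
                 pae_between = pae_between, pae_disorder = pae_disorder,
                 plddt_ordered = plddt_ordered,
                 plddt_disordered = plddt_disordered,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# --- idealised Calpha geometries -------------------------------------------

# Ideal alpha helix: rise 1.5 A/residue, radius 2.3 A, 100 degrees/residue.
# Gives d(i,i+2) ~ 5.4 A and d(i,i+3) ~ 5.1 A, inside the helix windows of
# the SSE detector.
helix_coords <- function(n, rise = 1.5, radius = 2.3, twist_deg = 100) {
  t <- seq_len(n) - 1L
  th <- t * twist_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * t)
}

# Ideal beta strand: 3.3 A axial step with a 0.9 A pleat, giving
# d(i,i+2) ~ 6.6 A and d(i,i+3) ~ 10.1 A, inside the strand windows.
strand_coords <- function(n, step = 3.3, pleat = 0.9) {
  t <- seq_len(n) - 1L
  cbind(step * t, pleat * (-1)^t, rep(0, n))
}

# Straight connector between two anchor points; spacing is whatever the gap
# dictates, which keeps connectors out of both SSE distance windows for the
# anchor separations used below.
connector_coords <- function(from, to, n) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  f <- seq_len(n) / (n + 1)
  cbind(from[1] + f * (to[1] - from[1]),
        from[2] + f * (to[2] - from[2]),
        from[3] + f * (to[3] - from[3]))
}

# Local coordinates of one globular block.
block_coords <- function(kind, geometry, len) {
  if (kind == "simple_helix") return(helix_coords(len))
  build_units <- function(n_units, unit_fun, unit_gap, loop_len, flip) {
    lens <- rep((len - loop_len * (n_units - 1L)) %/% n_units, n_units)
    lens[n_units] <- lens[n_units] +
      (len - loop_len * (n_units - 1L)) - sum(lens)
    coords <- NULL
    for (u in seq_len(n_units)) {
      xyz <- unit_fun(lens[u])
      if (flip && u %% 2L == 0L) xyz[, 3] <- max(xyz[, 3]) - xyz[, 3]
      xyz[, 1] <- xyz[, 1] + unit_gap * (u - 1L)
      if (u > 1L) {
        loop <- connector_coords(coords[nrow(coords), ], xyz[1L, ], loop_len)
        coords <- rbind(coords, loop)
      }
      coords <- rbind(coords, xyz)
    }
    coords
  }
  switch(geometry,
    helix_bundle = {
      n_h <- if (len > 90) 4L else 3L
      build_units(n_h, helix_coords, unit_gap = 10, loop_len = 5L,
                  flip = TRUE)
    },
    sheet_sandwich = {
      build_units(4L, function(n) {
        xyz <- strand_coords(n)
        xyz[, c(3, 1)] <- xyz[, c(1, 3)]   # strand axis along z
        xyz
      }, unit_gap = 4.8, loop_len = 4L, flip = TRUE)
    },
    mixed = {
      # two helices and two strands, each long enough for an SSE run
      usable <- len - 3L * 4L
      h_len <- max(10L, as.integer(round(usable * 0.3)))
      s_len <- (usable - 2L * h_len) %/% 2L
      lens <- c(h_len, s_len, h_len, usable - 2L * h_len - s_len)
      coords <- NULL
      for (u in 1:4) {
        xyz <- if (u %% 2L == 1L) helix_coords(lens[u]) else {
          z <- strand_coords(lens[u])
          z[, c(3, 1)] <- z[, c(1, 3)]
          z
        }
        xyz[, 1] <- xyz[, 1] + 8 * (u - 1L)
        if (u %% 2L == 0L) xyz[, 3] <- max(xyz[, 3]) - xyz[, 3]
        if (!is.null(coords)) {
          loop <- connector_coords(coords[nrow(coords), ], xyz[1L, ], 4L)
          coords <- rbind(coords, loop)
        }
        coords <- rbind(coords, xyz)
      }
      coords
    },
    stop("unknown geometry: ", geometry))
}

# Self-avoiding random coil: 3.8 A steps in random directions, rejecting
# steps that land within 3.0 A of any previously placed Calpha.
coil_coords <- function(n, start, existing, step = 3.8, clash = 3.0,
                        max_try = 60L) {
  out <- matrix(NA_real_, n, 3)
  prev <- start
  for (i in seq_len(n)) {
    best <- NULL
    best_min <- -Inf
    for (k in seq_len(max_try)) {
      v <- stats::rnorm(3)
      cand <- prev + step * v / sqrt(sum(v^2))
      pts <- rbind(existing, out[seq_len(i - 1L), , drop = FALSE])
      dmin <- if (nrow(pts)) {
        sqrt(min(rowSums(sweep(pts, 2, cand)^2)))
      } else Inf
      if (dmin >= clash) { best <- cand; break }
      if (dmin > best_min) { best <- cand; best_min <- dmin }
    }
    out[i, ] <- best
    prev <- best
  }
  out
}

#' Generate a synthetic predicted model with ground truth
#'
#' Builds Calpha coordinates block by block (ideal helix/strand geometry for
#' globular blocks, a self-avoiding random coil for linkers and disordered
#' tails), samples pLDDT from the ordered or disordered distribution, and
#' fills the PAE matrix from the within/between/disorder distributions
#' according to block membership (entries clipped to \[0.2, 31.75\], the AFDB
#' payload maximum; the matrix is sampled cell-wise and therefore
#' asymmetric, as real payloads are).
#'
#' @param spec A [synthetic_spec()].
#' @param model_id Accession for the generated model.
#' @return A list with elements `model` (a [predicted_model()] with PAE) and
#'   `truth` (class `ground_truth`: per-residue `labels`, the true domain
#'   `partition`, and the expanded `blocks` table).
#' @export
generate_model <- function(spec, model_id = "SYN0001") {
  stopifnot(inherits(spec, "synthetic_spec"))
  b <- spec$blocks
  n <- sum(b$length)
  withr::with_seed(spec$seed, {
    coords <- matrix(numeric(0), ncol = 3)
    cursor <- 0
    block_of <- integer(0)
    for (k in seq_len(nrow(b))) {
      len <- as.integer(b$length[k])
      if (b$kind[k] %in% c("domain", "simple_helix")) {
        xyz <- block_coords(b$kind[k], b$geometry[k], len)
        xyz[, 1] <- xyz[, 1] - min(xyz[, 1]) + cursor
        cursor <- max(xyz[, 1]) + 30
      } else {
        start <- if (nrow(coords)) coords[nrow(coords), ] else c(cursor, 0, 0)
        xyz <- coil_coords(len, start, coords)
        cursor <- max(cursor, max(xyz[, 1]) + 30)
      }
      coords <- rbind(coords, xyz)
      block_of <- c(block_of, rep(k, len))
    }
    # Linkers and tails are both non-globular for PAE purposes, but only
    # tails are low-confidence: a flexible linker is a confidently
    # predicted non-globular region.
    disordered <- b$kind[block_of] %in% c("linker", "disordered_tail")
    plddt_dis <- b$kind[block_of] == "disordered_tail"
    plddt <- ifelse(plddt_dis,
                    stats::rnorm(n, spec$plddt_disordered[1],
                                 spec$plddt_disordered[2]),
                    stats::rnorm(n, spec$plddt_ordered[1],
                                 spec$plddt_ordered[2]))
    plddt <- pmin(100, pmax(0, plddt))
    same_block <- outer(block_of, block_of, "==")
    any_dis <- outer(disordered, disordered, "|")
    pae <- matrix(stats::rnorm(n * n, spec$pae_between[1],
                               spec$pae_between[2]), n, n)
    n_within <- sum(same_block & !any_dis)
    pae[same_block & !any_dis] <- stats::rnorm(n_within, spec$pae_within[1],
                                               spec$pae_within[2])
    pae[any_dis] <- stats::rnorm(sum(any_dis), spec$pae_disorder[1],
                                 spec$pae_disorder[2])
    pae <- pmin(pmax(pae, 0.2), 31.75)
    diag(pae) <- stats::runif(n, 0.2, 1)
    sequence <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                             n, replace = TRUE), collapse = "")
    label_map <- c(linker = "FLEXIBLE", disordered_tail = "LOW_CONFIDENCE",
                   simple_helix = "SIMPLE")
    scen_map <- c(assigned = "ASSIGNED", unassigned = "UNASSIGNED",
                  partial = "PARTIAL")
    labels <- character(n)
    ends <- cumsum(b$length)
    starts <- ends - b$length + 1L
    for (k in seq_len(nrow(b))) {
      labels[starts[k]:ends[k]] <- if (b$kind[k] == "domain") {
        scen_map[[b$scenario[k]]]
      } else label_map[[b$kind[k]]]
    }
    dom <- which(b$kind == "domain")
    partition <- data.frame(start = starts[dom], end = ends[dom],
                            group_id = b$group_id[dom],
                            scenario = b$scenario[dom],
                            stringsAsFactors = FALSE)
    truth <- structure(list(labels = labels, partition = partition,
                            blocks = cbind(b, start = starts, end = ends)),
                       class = "ground_truth")
    model <- predicted_model(model_id, sequence, coords, plddt, pae)
    list(model = model, truth = truth)
  })
}

#' Generate a mock homology-hit table for a ground truth
#'
#' Emits, for every true domain block that is not in the `unassigned`
#' scenario, one sequence-profile and one structure-alignment hit to a
#' member of its true H-group. Confidence is drawn near 0.92 and reference
#' coverage near 0.85 (near 0.3 for `partial`-scenario blocks, emulating a
#' confident link without a high-coverage alignment). Decoy hits to random
#' wrong groups are added per block at rate `decoy_rate`, with confidence
#' uniform on \[0.1, 0.5\].
#'
#' @param truth A `ground_truth` object from [generate_model()].
#' @param catalog Reference catalog containing every true group.
#' @param query_id Model accession recorded in the hits.
#' @param conf Sampler parameters: list with `confidence` (mean, sd),
#'   `coverage` (mean, sd), `partial_coverage` (mean, sd).
#' @param decoy_rate Per-block probability of one decoy hit.
#' @param seed Integer seed.
#' @return A hit data frame (see [read_hits()]).
#' @export
generate_hits <- function(truth, catalog, query_id = "SYN0001",
                          conf = list(confidence = c(0.92, 0.04),
                                      coverage = c(0.85, 0.05),
                                      partial_coverage = c(0.30, 0.05)),
                          decoy_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  p <- truth$partition
  unknown <- setdiff(p$group_id, catalog$h_group)
  if (length(unknown))
    stop("true group(s) absent from catalog: ",
         paste(unknown, collapse = ", "))
  withr::with_seed(as.integer(seed), {
    rows <- list()
    clip01 <- function(x) pmin(1, pmax(0, x))
    for (k in seq_len(nrow(p))) {
      if (p$scenario[k] == "unassigned") next
      members <- catalog$domain_id[catalog$h_group == p$group_id[k]]
      covp <- if (p$scenario[k] == "partial") conf$partial_coverage else
        conf$coverage
      for (src in c("sequence_profile", "structure_align")) {
        jit <- sample(0:2, 2, replace = TRUE)
        qs <- min(p$start[k] + jit[1], p$end[k])
        qe <- max(p$end[k] - jit[2], qs)
        rows[[length(rows) + 1L]] <- data.frame(
          source = src, query_id = query_id,
          query_range = paste0(qs, "-", qe),
          ref_domain_id = sample(members, 1L),
          ref_group_id = p$group_id[k],
          confidence = clip01(stats::rnorm(1, conf$confidence[1],
                                           conf$confidence[2])),
          ref_coverage = clip01(stats::rnorm(1, covp[1], covp[2])),
          stringsAsFactors = FALSE)
      }
      if (stats::runif(1) < decoy_rate) {
        wrong <- setdiff(unique(catalog$h_group), p$group_id[k])
        if (length(wrong)) {
          rows[[length(rows) + 1L]] <- data.frame(
            source = sample(c("sequence_profile", "structure_align"), 1L),
            query_id = query_id,
            query_range = paste0(p$start[k], "-", p$end[k]),
            ref_domain_id = sample(
              catalog$domain_id[catalog$h_group %in% wrong], 1L),
            ref_group_id = sample(wrong, 1L),
            confidence = stats::runif(1, 0.1, 0.5),
            ref_coverage = stats::runif(1, 0.3, 0.9),
            stringsAsFactors = FALSE)
        }
      }
    }
    hits <- if (length(rows)) do.call(rbind, rows) else
      utils::read.delim(text = paste(
        c("source", "query_id", "query_range", "ref_domain_id",
          "ref_group_id", "confidence", "ref_coverage"), collapse = "\t"))
    validate_hits(hits)
    hits
  })
}

#' Default residue-category mix
#'
#' Residue-weighted target fractions for the six categories, matching the
#' coverage profile typical of whole predicted proteomes: about two thirds
#' confidently assigned, with the remainder split among flexible linkers,
#' low-confidence regions, and small unassigned/partial/simple fractions.
#'
#' @return Named numeric vector over the six categories, summing to 1.
#' @export
default_mix <- function() {
  c(assigned = 0.66, unassigned = 0.04, partial = 0.01, simple = 0.04,
    flexible = 0.12, low_confidence = 0.13)
}

#' Generate a synthetic proteome
#'
#' Draws `n_models` chain specs whose expected residue-category fractions
#' match `mix`. Each model holds three globular slots (domain or simple
#' blocks, kinds drawn with probability proportional to `mix`/block length)
#' separated by flexible linkers, plus a disordered tail; linker and tail
#' lengths are solved from the flexible and low-confidence weights. A shared
#' reference catalog and per-model hit tables are generated consistently
#' with the ground truth.
#'
#' @param n_models Number of models (at least 1).
#' @param mix Named weights over `assigned`, `unassigned`, `partial`,
#'   `simple`, `flexible`, `low_confidence`; must sum to 1.
#' @param seed Integer master seed; all per-model seeds derive from it.
#' @param n_groups H-groups in the generated catalog.
#' @param decoy_rate Decoy-hit rate passed to [generate_hits()].
#' @param domain_len,simple_len Globular block lengths (residues).
#' @return A list with `models`, `truths` (parallel lists), `hits` (one
#'   combined data frame), `catalog`, `expected_fractions` (realised
#'   ground-truth residue fractions of the drawn specs) and `mix`.
#' @export
generate_proteome <- function(n_models, mix = default_mix(), seed = 7L,
                              n_groups = 20L, decoy_rate = 0.1,
                              domain_len = 60L, simple_len = 30L) {
  if (n_models < 1) stop("n_models must be >= 1")
  full <- stats::setNames(numeric(6), names(default_mix()))
  if (is.null(names(mix)) || !all(names(mix) %in% names(full)))
    stop("mix names must be among: ", paste(names(full), collapse = ", "))
  full[names(mix)] <- mix
  if (abs(sum(full) - 1) > 1e-8) stop("mix weights must sum to 1")
  glob <- c(assigned = domain_len, unassigned = domain_len,
            partial = domain_len, simple = simple_len)
  wg <- sum(full[names(glob)])
  if (wg <= 0) stop("mix must put weight on at least one globular category")
  q <- (full[names(glob)] / glob)
  q <- q / sum(q)
  n_slots <- 3L
  exp_glob <- n_slots * sum(q * glob)
  total <- exp_glob / wg
  linker_len <- max(0L, as.integer(round(full[["flexible"]] * total / 2)))
  tail_len <- max(0L, as.integer(round(full[["low_confidence"]] * total)))
  withr::with_seed(as.integer(seed), {
    catalog <- make_reference_catalog(n_groups,
                                      seed = sample.int(2^31 - 1L, 1L))
    model_seeds <- sample.int(2^31 - 1L, n_models)
    hit_seeds <- sample.int(2^31 - 1L, n_models)
    geoms <- c("helix_bundle", "sheet_sandwich", "mixed")
    groups <- unique(catalog$h_group)
    specs <- lapply(seq_len(n_models), function(i) {
      kinds <- sample(names(glob), n_slots, replace = TRUE, prob = q)
      blocks <- list()
      for (s in seq_len(n_slots)) {
        blocks[[length(blocks) + 1L]] <- data.frame(
          kind = if (kinds[s] == "simple") "simple_helix" else "domain",
          length = unname(glob[[kinds[s]]]),
          group_id = if (kinds[s] == "simple") NA_character_ else
            sample(groups, 1L),
          geometry = sample(geoms, 1L),
          scenario = if (kinds[s] == "simple") NA_character_ else kinds[s],
          stringsAsFactors = FALSE)
        if (s < n_slots && linker_len > 0L)
          blocks[[length(blocks) + 1L]] <- data.frame(
            kind = "linker", length = linker_len, group_id = NA_character_,
            geometry = NA_character_, scenario = NA_character_,
            stringsAsFactors = FALSE)
      }
      if (tail_len > 0L)
        blocks[[length(blocks) + 1L]] <- data.frame(
          kind = "disordered_tail", length = tail_len,
          group_id = NA_character_, geometry = NA_character_,
          scenario = NA_character_, stringsAsFactors = FALSE)
      synthetic_spec(do.call(rbind, blocks), seed = model_seeds[i])
    })
    models <- vector("list", n_models)
    truths <- vector("list", n_models)
    hit_tabs <- vector("list", n_models)
    for (i in seq_len(n_models)) {
      id <- sprintf("SYN%04d", i)
      gm <- generate_model(specs[[i]], model_id = id)
      models[[i]] <- gm$model
      truths[[i]] <- gm$truth
      hit_tabs[[i]] <- generate_hits(gm$truth, catalog, query_id = id,
                                     decoy_rate = decoy_rate,
                                     seed = hit_seeds[i])
    }
    names(models) <- names(truths) <- vapply(models, `[[`, "", "model_id")
    all_labels <- unlist(lapply(truths, `[[`, "labels"))
    lab_key <- c(ASSIGNED = "assigned", UNASSIGNED = "unassigned",
                 PARTIAL = "partial", SIMPLE = "simple",
                 FLEXIBLE = "flexible", LOW_CONFIDENCE = "low_confidence")
    frac <- table(factor(lab_key[all_labels], levels = names(full)))
    expected_fractions <- as.numeric(frac) / length(all_labels)
    names(expected_fractions) <- names(full)
    list(models = models, truths = truths,
         hits = do.call(rbind, hit_tabs), catalog = catalog,
         expected_fractions = expected_fractions, mix = full)
  })
}

#' Synthetic sequence families for clustering tests
#'
#' Generates `n_families` unrelated parent sequences (lengths drawn from
#' `len_range`) and derives each family's members by point substitutions at
#' rate `mut_rate`, so that within-family identity is high (about
#' `1 - mut_rate` per pair of mutated positions) and between-family local
#' identity is at background level.
#'
#' @param n_families,members_per_family Family count and size.
#' @param seed Integer seed.
#' @param len_range Length-2 integer range of parent lengths.
#' @param mut_rate Per-position substitution probability for members.
#' @return Data frame with columns `id`, `sequence`, `family`.
#' @export
make_sequence_families <- function(n_families = 10L, members_per_family = 10L,
                                   seed = 9L, len_range = c(80L, 150L),
                                   mut_rate = 0.05) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (f in seq_len(n_families)) {
      len <- sample(len_range[1]:len_range[2], 1L)
      parent <- sample(aa, len, replace = TRUE)
      for (m in seq_len(members_per_family)) {
        s <- parent
        mut <- which(stats::runif(len) < mut_rate)
        if (length(mut))
          s[mut] <- sample(aa, length(mut), replace = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("F%02dM%02d", f, m),
          sequence = paste(s, collapse = ""),
          family = sprintf("F%02d", f), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
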