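#' Read a predicted model from mmCIF or PDB
#'
#' Reads one chain's Calpha trace. Per-residue pLDDT is taken from the
#' B-factor column, following the AlphaFold Database convention; files whose
#' B-factors exceed 100 are rejected as non-AFDB. The returned model has no
#' PAE attached (see [read_pae_json()]).
#'
#' @param path Path to a `.cif`/`.mmcif` or `.pdb`/`.ent` file.
#' @param chain Chain identifier; by default the first chain in the file.
#' @param model_id Accession to record; defaults to the file stem.
#' @return A [predicted_model()] without PAE. Residues lacking a Calpha atom
#'   are skipped; their count is available as `attr(x, "parse_report")`.
#' @export
read_model <- function(path, chain = NULL, model_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- if (is_cif) {
    suppressWarnings(bio3d::read.cif(path))
  } else {
    suppressWarnings(bio3d::read.pdb(path))
  }
  atoms <- pdb$atom
  chains <- unique(atoms$chain)
  if (is.null(chain)) chain <- chains[1L]
  if (!chain %in% chains) stop("chain not found: ", chain)
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  n_res_total <- length(unique(atoms$resno))
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  n_skipped <- n_res_total - nrow(ca)
  if (n_skipped > 0L)
    warning(n_skipped, " residue(s) lacking a Calpha atom were skipped")
  if (nrow(ca) == 0L) stop("no Calpha atoms on chain ", chain)
  if (any(ca$b > 100))
    stop("B-factors exceed 100; not an AFDB-convention confidence field")
  seq1 <- paste(bio3d::aa321(ca$resid), collapse = "")
  if (is.null(model_id))
    model_id <- sub("\\.(cif|mmcif|pdb|ent)$", "", basename(path),
                    ignore.case = TRUE)
  m <- predicted_model(model_id = model_id, sequence = seq1,
                       ca_coords = cbind(ca$x, ca$y, ca$z), plddt = ca$b)
  attr(m, "parse_report") <- list(chain = chain, n_residues = nrow(ca),
                                  n_skipped_no_ca = n_skipped)
  m
}

#' Write a predicted model to mmCIF or PDB
#'
#' Emits a Calpha-only single-chain file with pLDDT in the B-factor column.
#' The format is chosen from the file extension. Coordinates and B-factors
#' are written at fixed precision, so a write/read round trip reproduces the
#' model up to 3 (coordinates) and 2 (pLDDT) decimals.
#'
#' @param model A [predicted_model()].
#' @param path Output path ending in `.cif` or `.pdb`.
#' @param chain Chain identifier to write. Default `"A"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, chain = "A") {
  stopifnot(inherits(model, "predicted_model"))
  n <- model_length(model)
  res3 <- bio3d::aa123(strsplit(model$sequence, "")[[1L]])
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
    hdr <- c(paste0("data_", model$model_id), "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                      "auth_comp_id", "auth_asym_id", "auth_atom_id",
                      "pdbx_PDB_model_num")))
    rows <- sprintf(
      "ATOM %d C CA . %s %s 1 %d ? %.3f %.3f %.3f 1.00 %.2f ? %d %s %s CA 1",
      seq_len(n), res3, chain, seq_len(n),
      model$ca_coords[, 1L], model$ca_coords[, 2L], model$ca_coords[, 3L],
      model$plddt, seq_len(n), res3, chain)
    writeLines(c(hdr, rows, "#"), path)
  } else {
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(model$ca_coords)),
                     resno = seq_len(n), resid = res3,
                     chain = rep(chain, n), elety = rep("CA", n),
                     b = model$plddt, o = rep(1, n))
  }
  invisible(path)
}

#' Read an AFDB predicted-aligned-error JSON payload
#'
#' Accepts the AlphaFold Database convention (a top-level list holding one
#' object with a `predicted_aligned_error` member) or a bare square matrix.
#' No symmetrisation is applied at read time.
#'
#' @param path Path to the JSON file.
#' @return An n x n numeric matrix.
#' @export
read_pae_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.list(x) && length(x) >= 1L && is.list(x[[1L]]) &&
      !is.null(x[[1L]][["predicted_aligned_error"]]))
    x <- x[[1L]][["predicted_aligned_error"]]
  if (!is.list(x) || length(x) == 0L) stop("malformed PAE")
  n <- length(x)
  rows <- lapply(x, function(r) {
    v <- unlist(r, use.names = FALSE)
    if (length(v) != n || !is.numeric(v)) stop("malformed PAE")
    as.numeric(v)
  })
  m <- do.call(rbind, rows)
  if (any(!is.finite(m)) || any(m < 0)) stop("malformed PAE")
  m
}

#' Write a PAE matrix in the AFDB JSON convention
#'
#' @param pae Square non-negative matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pae_json <- function(pae, path) {
  pae <- as.matrix(pae)
  stopifnot(nrow(pae) == ncol(pae), all(pae >= 0))
  payload <- list(list(
    predicted_aligned_error = lapply(seq_len(nrow(pae)),
                                     function(i) unname(pae[i, ])),
    max_predicted_aligned_error = 31.75))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a table of classified regions
#'
#' One row per region with columns `model_id`, `range`, `category`,
#' `h_group`, `score`, `mean_plddt`, `n_sse`. Rows are sorted by
#' `(model_id, range start)` and floats fixed at 4 decimals so diffs between
#' runs are stable.
#'
#' @param records Data frame of classified regions (see [classify_model()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(records, path) {
  cols <- c("model_id", "range", "category", "h_group", "score",
            "mean_plddt", "n_sse")
  if (nrow(records) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  stopifnot(all(c("model_id", "range", "category") %in% names(records)))
  for (opt in c("h_group", "score", "mean_plddt", "n_sse"))
    if (is.null(records[[opt]])) records[[opt]] <- NA
  start <- vapply(records$range, function(s) parse_range(s)[1L, 1L], 1L)
  records <- records[order(records$model_id, start), cols, drop = FALSE]
  fmt4 <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", as.numeric(x)))
  out <- data.frame(model_id = records$model_id, range = records$range,
                    category = records$category,
                    h_group = ifelse(is.na(records$h_group), "NA",
                                     as.character(records$h_group)),
                    score = fmt4(records$score),
                    mean_plddt = fmt4(records$mean_plddt),
                    n_sse = ifelse(is.na(records$n_sse), "NA",
                                   as.character(as.integer(records$n_sse))),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a classified-region table written by [write_domain_table()]
#' @param path TSV path.
#' @return Data frame with typed columns.
#' @export
read_domain_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "NA",
                          fileEncoding = "UTF-8")
  df$score <- as.numeric(df$score)
  df$mean_plddt <- as.numeric(df$mean_plddt)
  df$n_sse <- as.integer(df$n_sse)
  df
}

#' Read or write a homology-hit table
#'
#' Flat TSV emulating the output of sequence-profile and structure-alignment
#' searches: columns `source` (`sequence_profile` or `structure_align`),
#' `query_id`, `query_range`, `ref_domain_id`, `ref_group_id`, `confidence`,
#' `ref_coverage`.
#'
#' @param path TSV path.
#' @return `read_hits`: a data frame of hits.
#' @export
read_hits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  validate_hits(df)
  df
}

#' @rdname read_hits
#' @param hits Data frame of hits.
#' @export
write_hits <- function(hits, path) {
  validate_hits(hits)
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

validate_hits <- function(hits) {
  need <- c("source", "query_id", "query_range", "ref_domain_id",
            "ref_group_id", "confidence", "ref_coverage")
  if (!all(need %in% names(hits)))
    stop("hit table missing columns: ",
         paste(setdiff(need, names(hits)), collapse = ", "))
  if (nrow(hits)) {
    stopifnot(all(hits$source %in% c("sequence_profile", "structure_align")),
              all(hits$confidence >= 0 & hits$confidence <= 1),
              all(hits$ref_coverage >= 0 & hits$ref_coverage <= 1))
    lapply(hits$query_range, parse_range)
  }
  invisible(TRUE)
}

#' Read or write a reference domain catalog
#'
#' Flat TSV with one reference domain per row: `domain_id`, `f_group`,
#' `h_group`, `x_group`, `architecture`, `class5`, `length`, `kingdom`.
#' `class5` is one of the five structural classes `all-a`, `all-b`, `a/b`,
#' `a+b`, `few-SSE`.
#'
#' @param path TSV path.
#' @return `read_catalog`: a data frame; its `class5` values are validated
#'   against the closed five-class set and `domain_id` must be unique.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  validate_catalog(df)
  df
}

#' @rdname read_catalog
#' @param catalog Data frame of reference domains.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The five structural classes of the reference hierarchy
#' @return Character vector of the closed class set.
#' @export
class5_levels <- function() c("all-a", "all-b", "a/b", "a+b", "few-SSE")

validate_catalog <- function(catalog) {
  need <- c("domain_id", "f_group", "h_group", "x_group", "architecture",
            "class5", "length", "kingdom")
  if (!all(need %in% names(catalog)))
    stop("catalog missing columns: ",
         paste(setdiff(need, names(catalog)), collapse = ", "))
  if (anyDuplicated(catalog$domain_id)) stop("duplicate domain_id in catalog")
  if (!all(catalog$class5 %in% class5_levels()))
    stop("class5 outside the closed five-class set")
  one_h <- tapply(catalog$h_group, catalog$domain_id,
                  function(h) length(unique(h)))
  stopifnot(all(one_h == 1L))
  invisible(TRUE)
}

#' Read or write an annotation-interval table
#'
#' Flat TSV subset of a bulk protein-to-domain annotation file: columns
#' `protein_id`, `entry_id`, `source_db`, `start`, `end` (1-based inclusive).
#'
#' @param path TSV path.
#' @return `read_annotations`: a data frame of intervals.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("protein_id", "entry_id", "source_db", "start", "end")
  if (!all(need %in% names(df)))
    stop("annotation table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  stopifnot(all(df$start <= df$end))
  df
}

#' @rdname read_annotations
#' @param annotations Data frame of intervals.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(all(annotations$start <= annotations$end))
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
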