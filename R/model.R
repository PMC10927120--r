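#' Predicted protein model
#'
#' One chain of a predicted structure: sequence, Calpha coordinates,
#' per-residue pLDDT (stored in the B-factor field by the AlphaFold Database
#' convention), and optionally the n x n predicted-aligned-error matrix.
#'
#' @param model_id Accession string.
#' @param sequence One-letter amino-acid string of length n.
#' @param ca_coords n x 3 numeric matrix of Calpha coordinates (Angstrom).
#' @param plddt Numeric vector of length n, values in \[0, 100\].
#' @param pae Optional n x n matrix of predicted aligned errors (Angstrom,
#'   non-negative, diagonal at most 1). May be asymmetric; symmetrisation
#'   happens only at feature-computation time.
#' @return An object of class `predicted_model`.
#' @export
predicted_model <- function(model_id, sequence, ca_coords, plddt, pae = NULL) {
  stopifnot(is.character(model_id), length(model_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  ca_coords <- matrix(as.numeric(ca_coords), ncol = 3)
  plddt <- as.numeric(plddt)
  if (nrow(ca_coords) != n || length(plddt) != n)
    stop("sequence, coordinates and plddt must agree in length")
  if (any(!is.finite(ca_coords))) stop("non-finite coordinate")
  if (any(plddt < 0 | plddt > 100))
    stop("plddt values must lie in [0, 100]")
  m <- structure(list(model_id = model_id, sequence = sequence,
                      ca_coords = ca_coords, plddt = plddt, pae = NULL),
                 class = "predicted_model")
  if (!is.null(pae)) m <- set_pae(m, pae)
  m
}

#' Attach a PAE matrix to a model
#'
#' @param model A [predicted_model()].
#' @param pae n x n non-negative matrix matching the model length; diagonal
#'   entries must not exceed 1 Angstrom.
#' @return The model with `$pae` set.
#' @export
set_pae <- function(model, pae) {
  stopifnot(inherits(model, "predicted_model"))
  pae <- as.matrix(pae)
  n <- model_length(model)
  if (nrow(pae) != n || ncol(pae) != n)
    stop("PAE matrix must be ", n, " x ", n)
  if (any(!is.finite(pae)) || any(pae < 0)) stop("malformed PAE")
  if (any(diag(pae) > 1)) stop("PAE diagonal exceeds 1 Angstrom")
  model$pae <- unname(pae)
  model
}

#' Number of residues in a model
#' @param model A [predicted_model()].
#' @return Integer length n.
#' @export
model_length <- function(model) {
  stopifnot(inherits(model, "predicted_model"))
  nchar(model$sequence)
}

#' @export
print.predicted_model <- function(x, ...) {
  cat("<predicted_model> ", x$model_id, ": ", model_length(x),
      " residues, mean pLDDT ", sprintf("%.1f", mean(x$plddt)),
      if (is.null(x$pae)) ", no PAE" else ", PAE attached", "\n", sep = "")
  invisible(x)
}

# Symmetrised PAE: mean of (i,j) and (j,i) entries.
pae_sym <- function(model) {
  if (is.null(model$pae)) stop("PAE required")
  (model$pae + t(model$pae)) / 2
}
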