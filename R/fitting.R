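# Datasets, train/test splitting, energy-window filtering, weighted
# linear least-squares fitting of PIP coefficients to energies (and,
# optionally, analytic Cartesian gradients), and RMSE reporting.

#' Create a PES dataset
#'
#' @param geometries list of [geometry()] objects.
#' @param energies numeric vector, one energy per geometry.
#' @param gradients optional numeric matrix, one 3N-row per geometry
#'   (atom-major component order), energy unit per Angstrom.
#' @param energy_unit unit of the energies (default `"cm-1"`).
#' @param tag `"unsplit"`, `"train"` or `"test"`.
#' @param provenance free-text note on where the data came from.
#' @return an object of class `pes_dataset`.
#' @export
pes_dataset <- function(geometries, energies, gradients = NULL,
                        energy_unit = "cm-1", tag = "unsplit",
                        provenance = "") {
  if (length(geometries) != length(energies))
    stop("need one energy per geometry")
  if (!all(is.finite(energies))) stop("energies must be finite")
  if (!is.null(gradients)) {
    gradients <- as.matrix(gradients)
    if (nrow(gradients) != length(energies))
      stop("need one gradient row per record")
    if (ncol(gradients) != 3 * n_atoms(geometries[[1]]))
      stop("gradient rows must have 3N components")
    if (!all(is.finite(gradients))) stop("gradients must be finite")
  }
  structure(list(geometries = geometries, energies = as.numeric(energies),
                 gradients = gradients, energy_unit = energy_unit,
                 tag = tag, provenance = provenance),
            class = "pes_dataset")
}

#' @export
print.pes_dataset <- function(x, ...) {
  cat(sprintf("<pes_dataset: %d records%s, unit %s, tag %s>\n",
              length(x$energies),
              if (is.null(x$gradients)) "" else " with gradients",
              x$energy_unit, x$tag))
  invisible(x)
}

#' @export
length.pes_dataset <- function(x) length(x$energies)

subset_dataset <- function(d, idx, tag = d$tag) {
  pes_dataset(d$geometries[idx], d$energies[idx],
              if (is.null(d$gradients)) NULL else d$gradients[idx, , drop = FALSE],
              energy_unit = d$energy_unit, tag = tag,
              provenance = d$provenance)
}

#' Split a dataset into train and test sets
#'
#' Deterministic seeded shuffle; the same seed always produces the same
#' partition (the seed is recorded in both halves' provenance).
#'
#' @param d a [pes_dataset()].
#' @param n_train number of training records (0 < n_train < number of
#'   records).
#' @param seed integer RNG seed.
#' @return list with elements `train` and `test`.
#' @export
split_dataset <- function(d, n_train, seed = 1L) {
  n <- length(d$energies)
  if (n_train <= 0 || n_train >= n)
    stop(sprintf("n_train must be in 1..%d", n - 1L))
  perm <- withr::with_seed(seed, sample.int(n))
  note <- sprintf("%s | split n_train=%d seed=%d", d$provenance, n_train, seed)
  tr <- subset_dataset(d, sort(perm[seq_len(n_train)]), tag = "train")
  te <- subset_dataset(d, sort(perm[(n_train + 1L):n]), tag = "test")
  tr$provenance <- note; te$provenance <- note
  list(train = tr, test = te)
}

#' Filter a dataset by energy above its minimum
#'
#' Keeps records whose energy lies within `e_max` of the dataset minimum,
#' preserving record order (the energy-cutoff protocol used to
#' concentrate a correction fit on the low-energy window).
#'
#' @param d a [pes_dataset()].
#' @param e_max window width above the dataset minimum, in the dataset's
#'   energy unit; must be positive (`Inf` keeps everything).
#' @return filtered `pes_dataset`; an empty result triggers a warning and
#'   is returned with zero records.
#' @export
filter_by_energy <- function(d, e_max) {
  if (!is.numeric(e_max) || e_max <= 0) stop("e_max must be positive")
  keep <- which(d$energies - min(d$energies) <= e_max)
  if (length(keep) == 0)
    warning("energy filter removed every record")
  subset_dataset(d, keep)
}

design_matrix <- function(basis, transform, d, gradient_weight = 1) {
  n <- length(d$energies)
  use_grad <- !is.null(d$gradients) && gradient_weight > 0
  n3 <- if (use_grad) 3 * n_atoms(d$geometries[[1]]) else 0L
  A <- matrix(0, n + n * n3, basis$n_p)
  b <- numeric(n + n * n3)
  w <- numeric(n + n * n3)
  for (r in seq_len(n)) {
    g <- d$geometries[[r]]
    y <- morse_variables(pair_distances(g), transform)
    A[r, ] <- evaluate_basis(basis, y)
    b[r] <- d$energies[r]
    w[r] <- 1
    if (use_grad) {
      rows <- n + (r - 1L) * n3 + seq_len(n3)
      A[rows, ] <- t(basis_cartesian_jacobian(basis, transform, g))
      b[rows] <- d$gradients[r, ]
      w[rows] <- gradient_weight
    }
  }
  list(A = A, b = b, w = w, n_energy = n, n_gradient = n * n3)
}

#' Fit a linear PIP potential by weighted least squares
#'
#' Builds the design matrix of basis values (one row per energy) plus,
#' when the dataset carries gradients and `gradient_weight > 0`, 3N
#' analytic-gradient rows per record, and minimizes the weighted sum of
#' squared residuals by a rank-revealing QR factorization.  Columns are
#' equilibrated to unit infinity-norm before the solve (undone on the
#' returned coefficients).  With `ridge = 0` and full column rank the
#' result is the exact least-squares minimizer; rank deficiency falls
#' back to the minimum-norm SVD solution with a warning.
#'
#' @param basis a [build_pip_basis()] object.
#' @param train training [pes_dataset()].
#' @param transform a [morse_transform()].
#' @param test optional held-out dataset for a test RMSE.
#' @param gradient_weight weight of each gradient-component row relative
#'   to an energy row (default 1).
#' @param ridge Tikhonov penalty on the scaled coefficients (default 0).
#' @return an object of class `fit_result`: the fitted
#'   [potential_model()] plus training/test RMSE (energy residuals only),
#'   row counts, a conditioning diagnostic, and an options echo.
#' @export
fit_linear <- function(basis, train, transform = morse_transform(),
                       test = NULL, gradient_weight = 1, ridge = 0) {
  if (length(train$energies) == 0) stop("empty training set")
  dm <- design_matrix(basis, transform, train, gradient_weight)
  sw <- sqrt(dm$w)
  A <- dm$A * sw
  b <- dm$b * sw
  scl <- apply(abs(A), 2, max)
  zero_col <- scl == 0
  if (any(zero_col)) {
    warning(sprintf("%d all-zero design column(s)", sum(zero_col)))
    scl[zero_col] <- 1
  }
  A <- sweep(A, 2, scl, "/")
  if (ridge > 0) {
    A <- rbind(A, diag(sqrt(ridge), ncol(A)))
    b <- c(b, numeric(ncol(A)))
  }
  qrd <- qr(A)
  rdiag <- abs(diag(qr.R(qrd)))
  tol <- max(dim(A)) * .Machine$double.eps * max(rdiag)
  rank <- sum(rdiag > tol)
  cond <- max(rdiag) / max(min(rdiag), .Machine$double.xmin)
  if (rank < ncol(A)) {
    warning(sprintf("rank-deficient design (rank %d of %d): returning the minimum-norm solution",
                    rank, ncol(A)))
    sv <- svd(A)
    keep <- sv$d > sv$d[1] * max(dim(A)) * .Machine$double.eps
    coefs <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
    coefs <- as.vector(coefs)
  } else {
    coefs <- qr.coef(qrd, b)
  }
  coefs <- coefs / scl
  model <- potential_model(basis, coefs, transform = transform,
                           energy_unit = train$energy_unit,
                           note = train$provenance)
  train_rep <- rmse_report(model, train)
  test_rep <- if (!is.null(test)) rmse_report(model, test) else NULL
  structure(list(model = model,
                 train_rmse = train_rep$rmse_energy,
                 test_rmse = if (is.null(test_rep)) NA_real_ else test_rep$rmse_energy,
                 n_records = dm$n_energy,
                 n_gradient_rows = dm$n_gradient,
                 rank = rank, condition = cond,
                 options = list(gradient_weight = gradient_weight,
                                ridge = ridge,
                                lambda_angstrom = transform$lambda)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %d PIPs, %d energies + %d gradient rows, train RMSE %.4g%s (%s), cond %.3g>\n",
              x$model$basis$n_p, x$n_records, x$n_gradient_rows,
              x$train_rmse,
              if (is.na(x$test_rmse)) "" else sprintf(", test RMSE %.4g", x$test_rmse),
              x$model$energy_unit, x$condition))
  invisible(x)
}

#' Fit a delta-ML correction surface
#'
#' Fits `basis_delta` to the residuals between high-level energies and a
#' low-level surface, E_HL(g) - V_LL(g), by [fit_linear()] using energy
#' rows only (the correction is trained without high-level gradients).
#' Composing the result with `v_ll` via [compose_delta()] gives the
#' corrected surface.
#'
#' @param v_ll low-level surface (any `pes_surface`); its energies are
#'   converted into the dataset's unit before the residuals are formed.
#' @param basis_delta PIP basis for the correction (typically much
#'   smaller than a full low-level basis).
#' @param hl high-level [pes_dataset()] (energies required, gradients
#'   ignored).
#' @param transform a [morse_transform()].
#' @param test optional held-out high-level dataset; the reported test
#'   RMSE is that of the correction against the held-out residuals.
#' @param ridge passed to [fit_linear()].
#' @return a `fit_result` whose model is the correction surface.
#' @export
fit_delta <- function(v_ll, basis_delta, hl, transform = morse_transform(),
                      test = NULL, ridge = 0) {
  resid_set <- function(d) {
    vll <- vapply(d$geometries, function(g)
      convert_energy(pes_energy(v_ll, g), v_ll$energy_unit, d$energy_unit),
      numeric(1))
    pes_dataset(d$geometries, d$energies - vll, gradients = NULL,
                energy_unit = d$energy_unit, tag = d$tag,
                provenance = paste(d$provenance, "| residuals vs low-level"))
  }
  fit_linear(basis_delta, resid_set(hl), transform = transform,
             test = if (is.null(test)) NULL else resid_set(test),
             gradient_weight = 0, ridge = ridge)
}

#' Energy RMSE of a surface against a dataset
#'
#' Residuals are surface minus reference, in the dataset's energy unit;
#' the RMSE is the root of the mean squared energy residual.
#'
#' @param surface any `pes_surface`.
#' @param d a [pes_dataset()].
#' @param shift_to_minimum if TRUE, also return reference energies
#'   shifted to the dataset minimum alongside the residuals (the
#'   convention used for residual-vs-energy plots).
#' @return list with `rmse_energy`, `residuals`, and (optionally)
#'   `energies_above_min`.
#' @export
rmse_report <- function(surface, d, shift_to_minimum = FALSE) {
  if (length(d$energies) == 0) stop("empty dataset")
  pred <- vapply(d$geometries, function(g)
    convert_energy(pes_energy(surface, g), surface$energy_unit,
                   d$energy_unit),
    numeric(1))
  res <- pred - d$energies
  out <- list(rmse_energy = sqrt(mean(res^2)), residuals = res)
  if (shift_to_minimum)
    out$energies_above_min <- d$energies - min(d$energies)
  out
}

# --- dataset file I/O ------------------------------------------------------

#' Write a dataset to a multi-frame XYZ plus sidecar table
#'
#' The geometries go to `<stem>.xyz`; energies (and gradient components,
#' if present) go to a tab-separated `<stem>.dat` with a commented header
#' recording units and provenance.
#'
#' @param d a [pes_dataset()].
#' @param stem output path stem (no extension).
#' @return character vector of the two file paths, invisibly.
#' @export
write_dataset <- function(d, stem) {
  xyz <- paste0(stem, ".xyz"); dat <- paste0(stem, ".dat")
  write_xyz(d$geometries, xyz)
  tab <- data.frame(index = seq_along(d$energies), energy = d$energies)
  if (!is.null(d$gradients)) {
    gcols <- as.data.frame(d$gradients)
    names(gcols) <- paste0("g", seq_len(ncol(gcols)))
    tab <- cbind(tab, gcols)
  }
  con <- file(dat, "w")
  writeLines(c(sprintf("# deltapes dataset; energy_unit=%s; gradients=%s",
                       d$energy_unit, !is.null(d$gradients)),
               sprintf("# provenance: %s", d$provenance),
               paste(names(tab), collapse = "\t")), con)
  utils::write.table(format(tab, digits = 17, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(c(xyz, dat))
}

#' Read a dataset written by [write_dataset()]
#'
#' @param stem path stem used at write time.
#' @return a [pes_dataset()].
#' @export
read_dataset <- function(stem) {
  xyz <- paste0(stem, ".xyz"); dat <- paste0(stem, ".dat")
  geoms <- read_xyz(xyz)
  hdr <- readLines(dat, n = 2)
  unit <- sub(".*energy_unit=([^;]+);.*", "\\1", hdr[1])
  prov <- sub("^# provenance: ", "", hdr[2])
  tab <- utils::read.table(dat, header = TRUE, sep = "\t", comment.char = "#",
                           skip = 2)
  grad <- NULL
  gcols <- grep("^g[0-9]+$", names(tab))
  if (length(gcols) > 0) grad <- as.matrix(tab[, gcols])
  pes_dataset(geoms, tab$energy, gradients = grad, energy_unit = unit,
              provenance = prov)
}
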