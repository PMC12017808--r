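# Synthetic stress-stretch curve generation and tabular curve I/O.

#' Assemble an experimental-style stress-stretch curve
#'
#' @param loadcase One of [LOAD_CASES].
#' @param state `"active"` or `"passive"`.
#' @param x Strictly increasing stretches (shear amounts for `SAF`).
#' @param P_kPa Nominal stresses (kPa).
#' @param model Optional model tag (free-text provenance).
#' @return A `data.frame` of class `experimental_curve`.
#' @export
experimental_curve <- function(loadcase, state, x, P_kPa, model = "data") {
  loadcase <- match.arg(loadcase, LOAD_CASES)
  state <- match.arg(state, c("active", "passive"))
  if (length(x) < 2L) stop("a curve needs at least 2 samples", call. = FALSE)
  if (is.unsorted(x, strictly = TRUE)) {
    stop("curve stretches must be strictly increasing", call. = FALSE)
  }
  if (length(P_kPa) != length(x)) stop("x and P_kPa lengths differ",
                                       call. = FALSE)
  structure(data.frame(
    loadcase = loadcase, state = state, model = model, x = x, P_kPa = P_kPa,
    stringsAsFactors = FALSE
  ), class = c("experimental_curve", "data.frame"))
}

# default per-mode grids spanning the ranges of the reported stress-stretch
# responses
default_mode_grids <- function(n = 25L) {
  list(
    UTCAF = seq(0.7, 1.5, length.out = n),
    UTCTF = seq(0.7, 1.3, length.out = n),
    SAF = seq(0.02, 0.4, length.out = n),
    PSAF = seq(0.8, 1.3, length.out = n),
    PSTF = seq(0.8, 1.3, length.out = n),
    PSTIF = seq(0.8, 1.3, length.out = n)
  )
}

#' Generate pseudo-experimental stress-stretch curves
#'
#' Evaluates the model response on per-mode grids and perturbs each sample
#' multiplicatively, `P * (1 + e)` with `e ~ Normal(0, noise_sd_rel)`.
#' Multiplicative noise keeps every mode informative in a fit even though
#' stress magnitudes differ by orders of magnitude across modes. The
#' default produces the passive six-mode set plus the active (tetanic)
#' uniaxial-along-fiber curve that mirrors the structure of the available
#' experimental data.
#'
#' @param params A `muscle_params` object.
#' @param modes Load cases for the passive curves.
#' @param grids Named list of per-mode grids; defaults to
#'   ranges typical of the reported responses.
#' @param active_utcaf Also generate the tetanic active UTCAF curve.
#' @param active_grid Grid for the active curve.
#' @param noise_sd_rel Relative noise standard deviation (0 = noiseless).
#' @param seed Integer seed for reproducibility.
#' @return List of [experimental_curve()] objects.
#' @export
generate_curves <- function(params, modes = LOAD_CASES,
                            grids = default_mode_grids(),
                            active_utcaf = TRUE,
                            active_grid = seq(0.6, 1.3, length.out = 25L),
                            noise_sd_rel = 0, seed = 1L) {
  stopifnot(noise_sd_rel >= 0)
  modes <- match.arg(modes, LOAD_CASES, several.ok = TRUE)
  set.seed(as.integer(seed))
  out <- list()
  for (mode in modes) {
    g <- grids[[mode]]
    sw <- response_sweep(params, mode, g, muscle_activation("passive"))
    P <- sw$P_kPa * (1 + stats::rnorm(length(g), 0, noise_sd_rel))
    out[[length(out) + 1L]] <- experimental_curve(mode, "passive", g, P,
                                                  params$model)
  }
  if (active_utcaf) {
    sw <- response_sweep(params, "UTCAF", active_grid,
                         muscle_activation("tetanic"))
    P <- sw$P_kPa * (1 + stats::rnorm(length(active_grid), 0, noise_sd_rel))
    out[[length(out) + 1L]] <- experimental_curve("UTCAF", "active",
                                                  active_grid, P,
                                                  params$model)
  }
  out
}

#' Write and read stress-stretch curves as tab-separated text
#'
#' Columns: `loadcase`, `state`, `model`, `x`, `P_kPa`. The round trip is
#' lossless to full double precision.
#'
#' @param curves List of [experimental_curve()] objects (or a single one).
#' @param path File path.
#' @return `read_curves` returns a list of `experimental_curve` objects.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "experimental_curve")) curves <- list(curves)
  tab <- do.call(rbind, lapply(curves, as.data.frame))
  tab$x <- sprintf("%.17g", tab$x)
  tab$P_kPa <- sprintf("%.17g", tab$P_kPa)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse curve file '%s': %s",
                                     path, conditionMessage(e)),
                             call. = FALSE)
  )
  needed <- c("loadcase", "state", "x", "P_kPa")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("curve file '%s' lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (is.null(tab$model)) tab$model <- "data"
  key <- paste(tab$loadcase, tab$state, tab$model)
  lapply(split(seq_len(nrow(tab)), factor(key, unique(key))), function(idx) {
    sub <- tab[idx, ]
    if (is.unsorted(sub$x, strictly = TRUE)) {
      first_bad <- idx[which(diff(sub$x) <= 0)[1] + 1L]
      stop(sprintf(
        "non-increasing stretch values in '%s' (data row %d)", path,
        first_bad
      ), call. = FALSE)
    }
    experimental_curve(sub$loadcase[1], sub$state[1], sub$x, sub$P_kPa,
                       sub$model[1])
  })
}
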