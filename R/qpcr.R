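#' Relative quantity by the 2^-ddCt method
#'
#' One threshold cycle (Ct) corresponds to a twofold difference in
#' template, so relative quantity follows from cycle differences:
#' dCt(test) = Ct(target, test) - Ct(reference, test), dCt(origin)
#' likewise for the originating line, ddCt = dCt(test) - dCt(origin),
#' and the relative quantity of the target in the test sample is
#' 2^-ddCt. A value of 1 means equal template, 2 means a doubling
#' (e.g. four chromosomal copies against two).
#'
#' @param ct_target_test,ct_ref_test Ct of the target and reference
#'   assays in the test sample.
#' @param ct_target_origin,ct_ref_origin same for the origin sample.
#' @return The relative quantity 2^-ddCt (vectorized).
#' @export
delta_delta_ct <- function(ct_target_test, ct_ref_test,
                           ct_target_origin, ct_ref_origin) {
  vals <- c(ct_target_test, ct_ref_test, ct_target_origin, ct_ref_origin)
  if (any(!is.finite(vals))) stop("non-finite Ct value")
  ddct <- (ct_target_test - ct_ref_test) -
    (ct_target_origin - ct_ref_origin)
  2^(-ddct)
}

#' Per-marker relative copy profile from a qPCR plate
#'
#' Collapses a replicate-structured plate to one relative quantity per
#' marker: within each (marker, sample, experiment), replicate Ct
#' values are averaged on the Ct scale (cycle noise is additive);
#' ddCt and R = 2^-ddCt are then computed per experiment against that
#' experiment's reference wells, and the marker's profile value is the
#' mean of R over experiments, with the between-experiment standard
#' deviation as dispersion.
#'
#' @param plate a `qpcr_plate` (see [qpcr_plate()]): long-format wells
#'   with marker order.
#' @return A `data.frame` of class `copy_profile`, one row per marker
#'   in panel order: `marker_id`, `R` (mean relative quantity),
#'   `R_sd` (sd across experiments), `n_experiments`.
#' @export
relative_copy_profile <- function(plate) {
  stopifnot(inherits(plate, "qpcr_plate"))
  wells <- plate$wells
  order_ids <- plate$marker_order
  experiments <- sort(unique(wells$experiment))
  # mean reference Ct per (sample, experiment)
  ref_ct <- function(smp, exp) {
    sel <- wells$target == "reference" & wells$sample == smp &
      wells$experiment == exp
    if (!any(sel)) {
      stop("missing reference wells for sample '", smp,
           "', experiment ", exp)
    }
    mean(wells$ct[sel])
  }
  rows <- lapply(order_ids, function(mk) {
    R_exp <- vapply(experiments, function(ex) {
      ct_of <- function(smp) {
        sel <- wells$target == "marker" & wells$marker_id == mk &
          wells$sample == smp & wells$experiment == ex
        if (!any(sel)) {
          stop("missing marker wells for '", mk, "', sample '", smp,
               "', experiment ", ex)
        }
        mean(wells$ct[sel])
      }
      delta_delta_ct(ct_of("test"), ref_ct("test", ex),
                     ct_of("origin"), ref_ct("origin", ex))
    }, numeric(1))
    data.frame(marker_id = mk, R = mean(R_exp),
               R_sd = stats::sd(R_exp),
               n_experiments = length(R_exp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("copy_profile", "data.frame")
  out
}

#' Assemble a qPCR plate object
#'
#' @param wells long-format `data.frame` with columns `marker_id`,
#'   `sample` ("test"/"origin"), `target` ("marker"/"reference"),
#'   `experiment`, `replicate`, `ct`.
#' @param marker_order character vector of marker ids in chromosomal
#'   order along the arm.
#' @return A list of class `qpcr_plate`.
#' @export
qpcr_plate <- function(wells, marker_order) {
  need <- c("marker_id", "sample", "target", "experiment", "replicate", "ct")
  if (!all(need %in% names(wells))) {
    stop("plate wells need columns: ", paste(need, collapse = ", "))
  }
  if (!all(wells$sample %in% c("test", "origin"))) {
    stop("sample must be 'test' or 'origin'")
  }
  if (!all(wells$target %in% c("marker", "reference"))) {
    stop("target must be 'marker' or 'reference'")
  }
  if (any(!is.finite(wells$ct)) || any(wells$ct <= 0)) {
    stop("Ct values must be finite and positive")
  }
  panel <- unique(wells$marker_id[wells$target == "marker"])
  missing <- setdiff(marker_order, panel)
  if (length(missing) > 0) {
    stop("marker(s) in panel order but absent from wells: ",
         paste(missing, collapse = ", "))
  }
  structure(list(wells = wells, marker_order = as.character(marker_order)),
            class = "qpcr_plate")
}

#' Read a qPCR plate from long-format CSV
#'
#' @param path CSV with header columns `marker_id`, `sample`,
#'   `target`, `experiment`, `replicate`, `ct`.
#' @param marker_order character vector, or path to a text file with
#'   one marker id per line, giving panel order.
#' @return A `qpcr_plate`.
#' @export
read_qpcr_plate <- function(path, marker_order) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (length(marker_order) == 1 && file.exists(marker_order)) {
    marker_order <- readLines(marker_order, warn = FALSE)
    marker_order <- marker_order[nzchar(marker_order)]
  }
  qpcr_plate(wells, marker_order)
}

#' Localize a copy-number breakpoint in an ordered marker profile
#'
#' Fits a single-step changepoint model to the log2 relative
#' quantities of an ordered marker panel by brute force: for every
#' changepoint j in 1..(n-1), the left and right segments are fitted
#' with their means of log2(R), and the j minimizing the residual sum
#' of squares is selected (SSE ties break toward smaller j). A step is
#' called only when the two-segment model beats the constant model by
#' BIC (Gaussian likelihood; the step model pays for one extra mean
#' plus the changepoint location). Fitted levels are reported both raw
#' (2^mean log2 R) and snapped to the nearest candidate copy-ratio
#' level (default {1, 2}, i.e. 2:2 vs 2:4 copies).
#'
#' @param profile a `copy_profile` from [relative_copy_profile()], or
#'   any data.frame with `marker_id` and `R` in panel order, or a bare
#'   numeric vector of relative quantities.
#' @param candidate_levels copy-ratio levels to snap to.
#' @return A list of class `breakpoint_call`: `changepoint` (index j:
#'   the step lies between marker j and j+1; NA when no step is
#'   called), `left_marker`/`right_marker` flanking ids (NA without a
#'   step), `left_level`, `right_level` (raw fitted), `left_call`,
#'   `right_call` (snapped), `sse`, `sse_constant`, `step_called`.
#' @export
detect_breakpoint <- function(profile, candidate_levels = c(1.0, 2.0)) {
  if (is.numeric(profile)) {
    profile <- data.frame(marker_id = as.character(seq_along(profile)),
                          R = profile)
  }
  R <- profile$R
  n <- length(R)
  if (n < 2) stop("breakpoint detection needs at least 2 markers")
  if (any(R <= 0)) stop("relative quantities must be positive")
  y <- log2(R)
  sse_of <- function(v) sum((v - mean(v))^2)
  sse1 <- sse_of(y)
  sse2 <- vapply(1:(n - 1), function(j) {
    sse_of(y[1:j]) + sse_of(y[(j + 1):n])
  }, numeric(1))
  j <- which.min(sse2)  # ties break toward smaller j
  # BIC with Gaussian errors: n*log(SSE/n) + k*log(n); guard SSE = 0
  # (noiseless data) with a floor well below any real Ct noise.
  eps <- 1e-12
  bic1 <- n * log(max(sse1, eps) / n) + 1 * log(n)
  bic2 <- n * log(max(sse2[j], eps) / n) + 3 * log(n)
  step_called <- bic2 < bic1
  snap <- function(lv) candidate_levels[which.min(abs(candidate_levels - lv))]
  if (step_called) {
    left <- 2^mean(y[1:j])
    right <- 2^mean(y[(j + 1):n])
    call <- list(changepoint = j,
                 left_marker = profile$marker_id[j],
                 right_marker = profile$marker_id[j + 1],
                 left_level = left, right_level = right,
                 left_call = snap(left), right_call = snap(right),
                 sse = sse2[j], sse_constant = sse1, step_called = TRUE)
  } else {
    lv <- 2^mean(y)
    call <- list(changepoint = NA_integer_,
                 left_marker = NA_character_, right_marker = NA_character_,
                 left_level = lv, right_level = lv,
                 left_call = snap(lv), right_call = snap(lv),
                 sse = sse1, sse_constant = sse1, step_called = FALSE)
  }
  structure(call, class = "breakpoint_call")
}
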