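# Wish-lists: ordered hard constraints plus prioritized objectives — the
# single optimization recipe shared by all planning modes.

wl_metrics_constraint <- c("max_dose", "min_dose", "mean_dose", "per_field_max_dose")
wl_metrics_objective <- c("mean_dose", "max_dose")

#' Parse and validate a wish-list
#'
#' A wish-list is JSON with two arrays. `constraints`: objects
#' `{structure, metric, bound, robust}` where metric is one of `max_dose`,
#' `min_dose`, `mean_dose`, `per_field_max_dose` and `bound` is in Gy_RBE.
#' `objectives`: objects `{priority, structure, metric, goal, sufficient,
#' robust}` with unique priorities contiguous from 1 and metric `mean_dose`
#' or `max_dose`. Robust items are enforced/evaluated in every scenario;
#' non-robust items in the nominal scenario only. Structure names are
#' checked against the phantom at plan time, not parse time.
#'
#' @param x JSON text, a file path, or a list with `constraints` and
#'   `objectives` data frames.
#' @return a `protonarc_wishlist`: list of two tibbles.
#' @export
#' @examples
#' wl <- parse_wishlist(default_wishlist())
#' wl$objectives$priority
parse_wishlist <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- if (file.exists(x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else jsonlite::fromJSON(x, simplifyVector = TRUE)
  }
  cons <- tibble::as_tibble(x$constraints)
  obj <- tibble::as_tibble(x$objectives)
  if (nrow(cons)) {
    cons$robust <- cons$robust %||% FALSE
    bad <- setdiff(cons$metric, wl_metrics_constraint)
    if (length(bad))
      stop_protonarc(sprintf("unknown constraint metric(s): %s",
                             paste(bad, collapse = ", ")), "protonarc_spec_error")
    if (any(cons$bound < 0))
      stop_protonarc("constraint bounds must be >= 0", "protonarc_spec_error")
  }
  if (nrow(obj)) {
    obj$sufficient <- obj$sufficient %||% FALSE
    obj$robust <- obj$robust %||% FALSE
    bad <- setdiff(obj$metric, wl_metrics_objective)
    if (length(bad))
      stop_protonarc(sprintf("unknown objective metric(s): %s",
                             paste(bad, collapse = ", ")), "protonarc_spec_error")
    if (anyDuplicated(obj$priority))
      stop_protonarc("objective priorities must be unique", "protonarc_spec_error")
    if (!identical(sort(as.integer(obj$priority)), seq_len(nrow(obj))))
      stop_protonarc("objective priorities must be contiguous from 1",
                     "protonarc_spec_error")
    if (any(obj$goal < 0))
      stop_protonarc("objective goals must be >= 0", "protonarc_spec_error")
    obj <- obj[order(obj$priority), ]
  }
  structure(list(constraints = cons, objectives = obj),
            class = "protonarc_wishlist")
}

#' The default (illustrative) wish-list
#'
#' Robust target minimum/maximum dose constraints, a robust serial-OAR
#' (cord) maximum, the 47 Gy per-field cap, and nominal-scenario-only
#' mean-dose OAR objectives ordered parotids, then constrictor, then a cord
#' maximum, then body mean dose (integral-dose surrogate). Goal values are
#' illustrative configuration, not a published protocol.
#'
#' @param prescription_gy prescription to the high-dose target (Gy_RBE).
#' @param elective_gy prescription to the elective target (Gy_RBE).
#' @return a list convertible by [parse_wishlist()].
#' @export
default_wishlist <- function(prescription_gy = 70, elective_gy = 54.25) {
  list(
    constraints = data.frame(
      structure = c("ctv70", "ctv70", "ctv5425", "ctv5425", "cord", "body"),
      metric = c("min_dose", "max_dose", "min_dose", "max_dose", "max_dose",
                 "per_field_max_dose"),
      bound = c(0.95 * prescription_gy, 1.15 * prescription_gy,
                0.95 * elective_gy, 1.15 * prescription_gy, 45, 47),
      robust = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
    objectives = data.frame(
      priority = 1:5,
      structure = c("parotid_l", "parotid_r", "constrictor", "cord", "body"),
      metric = c("mean_dose", "mean_dose", "mean_dose", "max_dose", "mean_dose"),
      goal = c(10, 10, 24, 32, 4),
      sufficient = c(FALSE, FALSE, FALSE, FALSE, FALSE),
      robust = FALSE)
  )
}

#' @exportS3Method base::print
print.protonarc_wishlist <- function(x, ...) {
  cat("<protonarc_wishlist>\nconstraints:\n")
  print(as.data.frame(x$constraints))
  cat("objectives:\n")
  print(as.data.frame(x$objectives))
  invisible(x)
}

#' Stable digest of a wish-list
#'
#' Used by studies to assert that every planning mode ran under the same
#' wish-list (the bias-free comparison contract).
#'
#' @param wishlist a `protonarc_wishlist`.
#' @return a short hash string.
#' @export
wishlist_digest <- function(wishlist) {
  rlang::hash(list(as.data.frame(wishlist$constraints),
                   as.data.frame(wishlist$objectives)))
}

#' Write a wish-list to JSON
#'
#' @param wishlist a `protonarc_wishlist` or default_wishlist()-style list.
#' @param path file path.
#' @export
write_wishlist <- function(wishlist, path) {
  jsonlite::write_json(list(constraints = as.data.frame(wishlist$constraints),
                            objectives = as.data.frame(wishlist$objectives)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
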