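#' Per-level trust state of a nurse
#'
#' Under the trust-based allocation policy every nurse keeps one trust weight
#' per difficulty level, updated from outcome feedback after each completed
#' task, plus a self-assessed reliability flag. Weights start from an
#' optimistic prior `w0`.
#'
#' @param w0 Initial trust weight in \[0,1\] for every level.
#' @param levels Difficulty levels tracked.
#' @return A list of class `ed_trust` with fields `weights`, `attempts`,
#'   `reliable`, `restricted_max_level`.
#' @export
trust_state <- function(w0 = 0.8, levels = PERFORMANCE_LEVELS) {
  stopifnot(w0 >= 0, w0 <= 1)
  structure(list(
    weights = stats::setNames(rep(as.numeric(w0), length(levels)), levels),
    attempts = stats::setNames(integer(length(levels)), levels),
    reliable = TRUE,
    restricted_max_level = NA_integer_
  ), class = "ed_trust")
}

#' Update a trust weight from a task outcome
#'
#' Exponential smoothing toward the binary outcome:
#' `w <- w + alpha * (outcome - w)` with outcome 1 for success, 0 for failure.
#' The weight stays in \[0,1\]; the attempt counter for the level is
#' incremented.
#'
#' @param state An [trust_state()].
#' @param level Difficulty level of the completed task.
#' @param success Logical outcome.
#' @param alpha Learning rate in (0, 1].
#' @return Updated trust state.
#' @examples
#' s <- trust_state(w0 = 0.5)
#' record_outcome(s, 3, TRUE, alpha = 0.2)$weights[["3"]] # 0.6
#' @export
record_outcome <- function(state, level, success, alpha = 0.2) {
  stopifnot(alpha > 0, alpha <= 1)
  level <- assert_level(level)
  k <- as.character(level)
  w <- state$weights[[k]]
  state$weights[[k]] <- w + alpha * (as.numeric(success) - w)
  state$attempts[[k]] <- state$attempts[[k]] + 1L
  state
}

#' Self-assess reliability against a trust threshold
#'
#' A nurse classifies itself unreliable when, for any level attempted at least
#' `min_attempts` times, the trust weight has fallen strictly below
#' `threshold` ("falls below" is strict; a weight equal to the threshold stays
#' reliable). On becoming unreliable the nurse restricts itself to levels at
#' or below `cap`. Idempotent.
#'
#' @param state An [trust_state()].
#' @param threshold Reliability threshold in (0, 1).
#' @param min_attempts Warm-up guard: levels with fewer attempts are not
#'   judged.
#' @param cap Restriction cap (maximum accepted level once unreliable).
#' @return Updated trust state.
#' @export
self_assess <- function(state, threshold = 0.5, min_attempts = 3L, cap = 2L) {
  stopifnot(threshold > 0, threshold < 1)
  cap <- assert_level(cap)
  judged <- state$attempts >= min_attempts
  failing <- judged & (state$weights < threshold)
  if (any(failing)) {
    state$reliable <- FALSE
    state$restricted_max_level <- cap
  }
  state
}

#' Pending-request store
#'
#' The broadcast mechanism appends every issued request to each nurse's local
#' store; claiming a request removes it from all stores, so the stores share
#' one pending pool. A store is a pair of parallel vectors (`request_id`,
#' `issue_time_s`) with each request appearing at most once.
#'
#' @param request_id Integer request identifiers.
#' @param issue_time_s Issue times in simulation seconds.
#' @return A list of class `ed_store`.
#' @export
request_store <- function(request_id = integer(), issue_time_s = numeric()) {
  stopifnot(length(request_id) == length(issue_time_s),
            !anyDuplicated(request_id))
  structure(list(request_id = as.integer(request_id),
                 issue_time_s = as.numeric(issue_time_s)),
            class = "ed_store")
}

select_oldest <- function(store, eligible) {
  idx <- which(eligible)
  if (!length(idx)) return(NA_integer_)
  ord <- order(store$issue_time_s[idx], store$request_id[idx])
  store$request_id[idx[ord[1L]]]
}

#' Trust-based request selection
#'
#' Returns the id of the oldest pending request whose requested level the
#' nurse currently accepts: all levels while self-assessed reliable, levels up
#' to `restricted_max_level` otherwise. Ties on issue time break toward the
#' lower request id. `NA` when no eligible request is pending (the nurse
#' idles).
#'
#' @param state An [trust_state()].
#' @param store An [request_store()].
#' @param requested_levels Integer lookup vector: `requested_levels[id]` is
#'   the requested level of request `id`.
#' @return A request id, or `NA_integer_`.
#' @export
select_request_ca <- function(state, store, requested_levels) {
  if (!length(store$request_id)) return(NA_integer_)
  lv <- requested_levels[store$request_id]
  if (anyNA(lv)) stop("dangling request id in store", call. = FALSE)
  # an unreliable nurse with no cap set (mentored training) keeps all levels
  eligible <- if (state$reliable || is.na(state$restricted_max_level)) {
    rep(TRUE, length(lv))
  } else {
    lv <= state$restricted_max_level
  }
  select_oldest(store, eligible)
}

#' First-in-first-out request selection
#'
#' Oldest pending request irrespective of level; ties on issue time break
#' toward the lower request id. `NA` on an empty store.
#'
#' @inheritParams select_request_ca
#' @return A request id, or `NA_integer_`.
#' @export
select_request_fifo <- function(store, requested_levels = NULL) {
  if (!length(store$request_id)) return(NA_integer_)
  if (!is.null(requested_levels) && anyNA(requested_levels[store$request_id])) {
    stop("dangling request id in store", call. = FALSE)
  }
  select_oldest(store, rep(TRUE, length(store$request_id)))
}
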