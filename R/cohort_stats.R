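# Cohort-level statistics: descriptive medians/quartiles, per-patient
# T2 - T1 deltas, and the 3 x 3 grid of Spearman rank correlations between
# affected-arm acceleration and the clinical scores.

#' Spearman rank correlation with permutation or t-approximate p-value
#'
#' Both vectors are converted to mid-ranks (average ranks on ties) and the
#' coefficient is the Pearson correlation of the rank vectors. The two-sided
#' p-value is computed by exact enumeration of all `n!` permutations when
#' `n <= exact_n_max` (feasible up to 9) and otherwise by the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom. Rank correlation is used because ordinal clinical
#' scores cannot be assumed normal.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, finite values.
#' @param exact_n_max largest `n` for which the exact permutation p-value is
#'   enumerated.
#' @return list with `rho`, `p_value`, `n` and `method`
#'   (`"exact-permutation"` or `"t-approximation"`).
#' @export
spearman_rho <- function(x, y, exact_n_max = 9L) {
  n <- length(x)
  if (length(y) != n) stop_shape("x and y differ in length")
  if (n < 3L) stop_too_short("need at least 3 complete pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop_format("values must be finite")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop_degenerate("constant input: rank variance is zero")
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_n_max) {
    p <- exact_spearman_pvalue(rx, ry, rho)
    method <- "exact-permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p_value = min(max(p, 0), 1), n = n, method = method)
}

# All permutations of 1..n as an n! x n matrix, built by inserting element k
# into every position of each permutation of 1..(k-1).
permutation_matrix <- function(n) {
  m <- matrix(1L, 1L, 1L)
  if (n == 1L) return(m)
  for (k in 2L:n) {
    blocks <- lapply(seq_len(k), function(pos) {
      cbind(m[, seq_len(pos - 1L), drop = FALSE],
            k,
            if (pos <= k - 1L) m[, pos:(k - 1L), drop = FALSE])
    })
    m <- do.call(rbind, blocks)
  }
  m
}

exact_spearman_pvalue <- function(rx, ry, rho_obs) {
  n <- length(rx)
  perms <- permutation_matrix(n)
  ry_perm <- matrix(ry[perms], nrow = nrow(perms))
  # Pearson correlation of rx with each permuted ry, vectorized over rows.
  sx <- sqrt(sum((rx - mean(rx))^2))
  sy <- sqrt(sum((ry - mean(ry))^2))
  cross <- as.numeric(ry_perm %*% rx) - n * mean(rx) * mean(ry)
  rho_all <- cross / (sx * sy)
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

#' Per-session descriptive statistics of a cohort table
#'
#' Median and quartiles (type-7 linear-interpolation quantiles) of the
#' clinical scores and the affected-arm mean acceleration, by test occasion.
#'
#' @param tbl data.frame with columns `session`, `mas`, `mal_aou`,
#'   `mal_qom`, `mean_affected`.
#' @return data.frame with one row per (session, variable) and columns
#'   `median`, `q1`, `q3`, `n`.
#' @export
cohort_descriptives <- function(tbl) {
  vars <- c("mas", "mal_aou", "mal_qom", "mean_affected")
  stopifnot(all(c("session", vars) %in% names(tbl)))
  sessions <- sort(unique(tbl$session))
  out <- do.call(rbind, lapply(sessions, function(s) {
    sub <- tbl[tbl$session == s, , drop = FALSE]
    if (nrow(sub) == 0L) stop_empty(sprintf("no rows for session %s", s))
    do.call(rbind, lapply(vars, function(v) {
      q <- stats::quantile(sub[[v]], probs = c(0.25, 0.5, 0.75),
                           type = 7, names = FALSE)
      data.frame(session = s, variable = v,
                 median = q[2], q1 = q[1], q3 = q[3], n = nrow(sub),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Per-patient T2 - T1 change table
#'
#' One row per patient with the change in affected-arm acceleration and in
#' each clinical score between the two test occasions (positive = improved).
#' Patients missing either occasion are excluded with a warning, mirroring
#' how incomplete participants are dropped from longitudinal analyses.
#'
#' @param tbl data.frame with columns `patient_id`, `session`,
#'   `mean_affected`, `mas`, `mal_aou`, `mal_qom`.
#' @return data.frame with columns `patient_id`, `d_accel_affected`,
#'   `d_mas`, `d_mal_aou`, `d_mal_qom`.
#' @export
delta_table <- function(tbl) {
  need <- c("patient_id", "session", "mean_affected", "mas", "mal_aou", "mal_qom")
  stopifnot(all(need %in% names(tbl)))
  complete <- intersect(tbl$patient_id[tbl$session == "T1"],
                        tbl$patient_id[tbl$session == "T2"])
  dropped <- setdiff(unique(tbl$patient_id), complete)
  if (length(dropped) > 0L) {
    warning(sprintf("excluding %d patient(s) without both sessions: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  out <- do.call(rbind, lapply(complete, function(pid) {
    t1 <- tbl[tbl$patient_id == pid & tbl$session == "T1", , drop = FALSE]
    t2 <- tbl[tbl$patient_id == pid & tbl$session == "T2", , drop = FALSE]
    data.frame(patient_id = pid,
               d_accel_affected = t2$mean_affected - t1$mean_affected,
               d_mas = t2$mas - t1$mas,
               d_mal_aou = t2$mal_aou - t1$mal_aou,
               d_mal_qom = t2$mal_qom - t1$mal_qom,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' The 3 x 3 correlation grid: scores x (T1, T2, delta)
#'
#' Spearman correlation of the affected-arm mean acceleration against each
#' clinical score (MAS, MAL amount-of-use, MAL quality-of-movement) at each
#' test occasion, plus the correlation of their T2 - T1 changes. No
#' multiple-testing correction is applied across the nine cells.
#'
#' @param tbl cohort table as for [delta_table()].
#' @return data.frame with columns `score`, `contrast`, `rho`, `p_value`,
#'   `n`, `method`.
#' @export
run_correlation_analysis <- function(tbl) {
  scores <- c("mas", "mal_aou", "mal_qom")
  deltas <- delta_table(tbl)
  cells <- expand.grid(score = scores, contrast = c("T1", "T2", "delta"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sc <- cells$score[i]; ct <- cells$contrast[i]
    if (ct == "delta") {
      x <- deltas$d_accel_affected
      y <- deltas[[paste0("d_", sc)]]
    } else {
      sub <- tbl[tbl$session == ct, , drop = FALSE]
      x <- sub$mean_affected
      y <- sub[[sc]]
    }
    res <- tryCatch(spearman_rho(x, y), bilatacc_degenerate_error = function(e) {
      stop_degenerate(sprintf("correlation cell %s/%s: %s", sc, ct, conditionMessage(e)))
    })
    data.frame(score = sc, contrast = ct, rho = res$rho,
               p_value = res$p_value, n = res$n, method = res$method,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
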