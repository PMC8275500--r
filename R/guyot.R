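#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Implements interval-wise allocation of events and censorings from digitized
#' Kaplan-Meier coordinates and the published numbers-at-risk table (the Guyot
#' algorithm). Within each risk-table interval the number of censored patients
#' is adjusted iteratively, with censoring times spread uniformly over the
#' interval, until the implied number at risk at the next risk-table time
#' matches the published count exactly. Event counts at each digitized time are
#' inferred from the drop in the survival fraction relative to the running
#' Kaplan-Meier product. When the total number of events is supplied, censoring
#' in the final interval is rescaled to match it; otherwise events in the final
#' interval are inferred from step heights alone and the patients still at risk
#' after the last digitized time are censored there.
#'
#' @param km A [digitized_km()] object; its risk table needs at least 2 rows.
#' @param total_events Optional integer: total number of events on the curve,
#'   if reported (e.g. in the publication text).
#'
#' @return A `pseudo_ipd` object: a data.frame with columns `time` (months)
#'   and `event` (1 = event, 0 = censored), one row per reconstructed patient.
#' @export
#' @examples
#' km <- digitized_km(c(0, 2, 5), c(1, 0.8, 0.4),
#'                    risk_time = c(0, 6), n_risk = c(10, 4))
#' reconstruct_ipd(km)
reconstruct_ipd <- function(km, total_events = NULL) {
  stopifnot(inherits(km, "digitized_km"))
  t <- km$curve$time
  S <- km$curve$survival
  Tr <- km$risk$time
  nr <- km$risk$n_risk
  K <- length(t)
  I <- length(Tr)
  if (I < 2L) stop("risk table needs at least 2 rows")
  eps <- 1e-9

  # first digitized index at/after each risk-table time (K+1 if none)
  lower <- vapply(Tr, function(x) {
    k <- which(t >= x - eps)
    if (length(k)) k[1] else K + 1L
  }, integer(1))
  lower <- c(lower, K + 1L)  # sentinel for the last interval

  n_hat <- numeric(K + 1)    # at risk just before t[k]
  d <- integer(K)            # events at t[k]
  cen_times <- vector("list", K)  # censor times in [t[k], t[k+1])
  n_hat[1] <- nr[1]
  km_last <- 1               # running KM estimate at the last event

  interval_end_time <- function(i) {
    if (lower[i + 1] <= K) t[lower[i + 1]] else max(t[K], Tr[min(i + 1, I)])
  }

  # process digitized indices ks given censor times; returns updated state
  process <- function(ks, ctimes, n0, km0, i) {
    d_i <- integer(length(ks))
    cen_i <- vector("list", length(ks))
    n <- n0; kml <- km0
    t_end <- interval_end_time(i)
    carry <- 0  # fractional-event remainder, so rounding does not drift
    for (j in seq_along(ks)) {
      k <- ks[j]
      dk <- 0L
      if (kml > 0 && S[k] < kml - eps) {
        d_exact <- n * (1 - S[k] / kml) + carry
        dk <- as.integer(round(d_exact))
        if (d_exact > n + 0.5)
          stop(sprintf(paste0("inconsistent risk table: implied events exceed",
                              " the number at risk in interval %d (t in [%g, %g])"),
                       i, Tr[i], t_end))
        dk <- max(0L, min(dk, as.integer(floor(n))))
        carry <- d_exact - dk
        if (dk > 0) kml <- kml * (1 - dk / n)
      }
      d_i[j] <- dk
      hi <- if (j < length(ks)) t[ks[j + 1]] else t_end
      ct <- ctimes[ctimes >= t[k] - eps & ctimes < hi - eps]
      # leftover censor times at/after the last subinterval fall in the last one
      if (j == length(ks)) ct <- ctimes[ctimes >= t[k] - eps]
      cen_i[[j]] <- ct
      n <- n - dk - length(ct)
      if (n < 0)
        stop(sprintf("inconsistent risk table in interval %d (t in [%g, %g])",
                     i, Tr[i], t_end))
    }
    list(d = d_i, cen = cen_i, n_end = n, km_last = kml)
  }

  spread <- function(nc, a, b) {
    if (nc <= 0) return(numeric(0))
    a + seq_len(nc) * (b - a) / (nc + 1)
  }

  # recompute n_end and the KM product from final event/censor allocations
  replay <- function(d_i, cen_i, n0, km0) {
    n <- n0; kml <- km0
    for (j in seq_along(d_i)) {
      if (d_i[j] > 0) kml <- kml * (1 - d_i[j] / n)
      n <- n - d_i[j] - length(cen_i[[j]])
    }
    list(n_end = n, km_last = kml)
  }

  for (i in seq_len(I - 1L)) {
    ks <- seq.int(lower[i], min(lower[i + 1] - 1L, K))
    if (lower[i] > K || length(ks) == 0L) next
    a <- t[lower[i]]; b <- interval_end_time(i)
    n0 <- n_hat[lower[i]]
    target <- nr[i + 1]
    eval_nc <- function(nc) process(ks, spread(nc, a, b), n0, km_last, i)
    # the number at risk at the interval end decreases (roughly one-for-one)
    # in the number censored: find the smallest censor count reaching the
    # published count, then reconcile the rounding remainder directly
    res <- eval_nc(0L)
    if (res$n_end > target) {
      nc <- res$n_end - target
      res <- eval_nc(nc)
      guard <- 0L
      while (res$n_end > target && nc < n0 && guard < 2L * n0) {
        nc <- nc + max(1L, res$n_end - target)
        res <- eval_nc(nc)
        guard <- guard + 1L
      }
      while (nc > 0L && eval_nc(nc - 1L)$n_end <= target) {
        nc <- nc - 1L
        res <- eval_nc(nc)
      }
    }
    deficit <- target - res$n_end
    if (deficit > max(2, round(0.02 * n0)))
      stop(sprintf(paste0("inconsistent risk table: implied events exceed ",
                          "the departures the risk table allows in interval ",
                          "%d (t in [%g, %g])"), i, Tr[i], b))
    if (deficit > 0) {
      # rounding removed too many patients: first drop censorings (latest
      # first), then events at the interval's last event times
      for (j in rev(seq_along(res$cen))) {
        take <- min(length(res$cen[[j]]), deficit)
        if (take > 0) {
          res$cen[[j]] <- res$cen[[j]][seq_len(length(res$cen[[j]]) - take)]
          deficit <- deficit - take
        }
        if (deficit == 0) break
      }
      if (deficit > 0) for (j in rev(which(res$d > 0))) {
        take <- min(res$d[j], deficit)
        res$d[j] <- res$d[j] - take
        deficit <- deficit - take
        if (deficit == 0) break
      }
    } else if (deficit < 0) {
      # still too many at risk: censor the excess at the interval end
      j <- length(res$cen)
      res$cen[[j]] <- c(res$cen[[j]], rep(b - (b - a) * 1e-6, -deficit))
      deficit <- 0L
    }
    rp <- replay(res$d, res$cen, n0, km_last)
    if (rp$n_end != target)
      stop(sprintf(paste0("inconsistent risk table: cannot match %d at risk",
                          " at t = %g (interval %d)"),
                   target, Tr[i + 1], i))
    d[ks] <- res$d
    cen_times[ks] <- res$cen
    km_last <- rp$km_last
    n_hat[if (lower[i + 1] <= K) lower[i + 1] else K + 1L] <- rp$n_end
  }

  # final interval: no known count to match
  n_left <- if (lower[I] <= K) {
    ks <- seq.int(lower[I], K)
    a <- t[lower[I]]; b <- interval_end_time(I)
    nc <- 0L
    res <- process(ks, numeric(0), n_hat[lower[I]], km_last, I)
    if (!is.null(total_events)) {
      # rescale censoring in the last interval to hit the reported event total
      target <- total_events - sum(d)
      for (iter in 1:60) {
        excess <- sum(res$d) - target
        if (excess <= 0 || nc + excess > n_hat[lower[I]]) break
        nc <- nc + as.integer(excess)
        res <- process(ks, spread(nc, a, b), n_hat[lower[I]], km_last, I)
      }
    }
    d[ks] <- res$d
    cen_times[ks] <- res$cen
    res$n_end
  } else n_hat[K + 1L]

  times <- c(rep(t, d), unlist(cen_times), rep(max(t[K], Tr[I]), n_left))
  event <- c(rep(1L, sum(d)),
             rep(0L, length(unlist(cen_times)) + n_left))
  o <- order(times, -event)
  pseudo_ipd(times[o], event[o], label = km$label)
}

#' Pseudo individual-patient data
#'
#' @param time Event/censoring times (months), non-negative.
#' @param event 1 for an event, 0 for censoring.
#' @param label Optional label.
#' @return A `pseudo_ipd` data.frame with columns `time` and `event`.
#' @export
pseudo_ipd <- function(time, event, label = "") {
  stopifnot(length(time) == length(event))
  if (any(time < 0)) stop("times must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event flags must be 0 or 1")
  structure(data.frame(time = as.numeric(time), event = as.integer(event)),
            label = label, class = c("pseudo_ipd", "data.frame"))
}

#' Read/write pseudo-IPD CSV (columns `time,event`)
#'
#' @param file Path to a CSV file.
#' @return `read_ipd()` returns a [pseudo_ipd()]; `write_ipd()` its input,
#'   invisibly.
#' @export
read_ipd <- function(file) {
  d <- utils::read.csv(file)
  if (!all(c("time", "event") %in% names(d)))
    stop("IPD file must have columns time,event")
  pseudo_ipd(d$time, d$event)
}

#' @param ipd A [pseudo_ipd()] object.
#' @rdname read_ipd
#' @export
write_ipd <- function(ipd, file) {
  utils::write.csv(as.data.frame(ipd)[c("time", "event")], file,
                   row.names = FALSE)
  invisible(ipd)
}
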