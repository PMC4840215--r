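# Independent oracles and small fixture builders used across the suite.

# Brute-force Victor-Purpura distance: minimum cost over all injective
# matchings between the two trains (matched spikes pay q|dt|, unmatched
# spikes pay 1 each). Exponential; for trains of <= 5 spikes only.
vp_brute <- function(x, y, q) {
  nx <- length(x); ny <- length(y)
  if (nx == 0) return(ny)
  if (ny == 0) return(nx)
  best <- nx + ny
  recurse <- function(i, avail, cost) {
    if (cost >= best) return(invisible())
    if (i > nx) {
      best <<- min(best, cost + sum(avail))
      return(invisible())
    }
    recurse(i + 1, avail, cost + 1)            # delete x[i]
    for (j in which(avail)) {
      a2 <- avail; a2[j] <- FALSE
      recurse(i + 1, a2, cost + q * abs(x[i] - y[j]))
    }
  }
  recurse(1, rep(TRUE, ny), 0)
  best
}

# random sorted spike train of n spikes on [0, span)
rand_times <- function(n, span = 1) sort(runif(n, 0, span))

# Brute-force interval components: transitive closure of pairwise overlap
# (closed intervals), independent of the sweep used by the package.
interval_components_brute <- function(starts, ends) {
  n <- length(starts)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    starts[i] <= ends[j] & starts[j] <= ends[i])
  comp <- seq_len(n)
  repeat {
    new <- comp
    for (i in seq_len(n)) new[i] <- min(comp[adj[i, ]])
    if (identical(new, comp)) break
    comp <- new
  }
  match(comp, unique(comp))
}

# Brute-force BH step-up rejection set
bh_brute <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  istar <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i * alpha / m) istar <- i
  rej <- logical(m)
  if (istar > 0) rej[ord[seq_len(istar)]] <- TRUE
  rej
}

# burstlets constructed directly (bypasses detection) for merge tests
mk_burstlet <- function(electrode, times) {
  list(electrode_id = electrode, spike_times = times,
       start = min(times), end = max(times))
}

# tiny recording with externally supplied per-electrode spike times
mk_recording <- function(times_by_electrode, n_tunnels = 51, t_stop = 10) {
  layout <- make_layout(n_tunnels)
  trains <- lapply(layout$electrodes$electrode_id, function(e) {
    ts <- times_by_electrode[[e]]
    spike_train(if (is.null(ts)) numeric(0) else ts, e, 1L, 0, t_stop)
  })
  names(trains) <- layout$electrodes$electrode_id
  structure(list(layout = layout, trains = trains, t_start = 0,
                 t_stop = t_stop, ground_truth = NULL, config = NULL),
            class = "mea_recording")
}
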