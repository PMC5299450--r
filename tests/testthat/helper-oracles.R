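# Independent oracles used against the package implementations.  These are
# deliberately written as plain loops / literal enumerations so they share
# no code path with the functions they check.

# Transition-counting constancy oracle: explicit loop, no vectorisation.
jacobs_ci_oracle <- function(rewards) {
  n <- length(rewards)
  same <- 0L
  for (i in 2:n) if (rewards[i] == rewards[i - 1]) same <- same + 1L
  cc <- same / (n - 1)
  p <- sum(rewards == "nectar") / n
  e <- p^2 + (1 - p)^2
  denom <- cc + e - 2 * cc * e
  if (denom == 0) return(NA_real_)
  (cc - e) / denom
}

# All 2^L nectar/pollen sequences of length L, as a list.
all_reward_sequences <- function(L) {
  grid <- expand.grid(rep(list(c("nectar", "pollen")), L),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ], use.names = FALSE))
}

# Literal 2^n sign-pattern enumeration of the signed-rank test.
wilcoxon_enumeration_oracle <- function(values, mu0 = 0,
                                        alternative = "greater") {
  d <- values - mu0
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p_ge <- mean(v_all >= v_obs - 1e-9)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  list(V = v_obs, p_value = p)
}

# Hand-built event stream: one read per row of (t, tag, reader).
make_events <- function(t, tag, reader) {
  tibble::tibble(timestamp = t,
                 tag_id = tag,
                 reader_id = reader)
}

# Events for a full clean visit of `tag` in chamber `chamber`, entering at
# `start` and leaving at `end` (pairing gap 2 s), written out read by read.
clean_visit_events <- function(tag, chamber, start, end, gap = 2) {
  make_events(
    t = c(start - gap, start, end, end + gap),
    tag = rep(tag, 4),
    reader = paste0(chamber, c("_outer", "_inner", "_inner", "_outer"))
  )
}

# Minimal bout table builder for specialization tests.
make_bouts <- function(tag_id, day, reward, start = NULL) {
  n <- length(reward)
  tibble::tibble(
    tag_id = rep_len(tag_id, n),
    day = rep_len(day, n),
    reward = reward,
    start = if (is.null(start)) seq_len(n) * 1000 else start,
    end = (if (is.null(start)) seq_len(n) * 1000 else start) + 300,
    duration_s = 300
  )
}
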