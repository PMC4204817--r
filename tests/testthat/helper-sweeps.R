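# Construct a synthetic triggered_sweeps object with independent Bernoulli
# spike indicators in the pre- and post-onset windows (spike times placed
# uniformly inside the window). Used to test the decoders against known
# (P_pre, P_post).
make_bernoulli_sweeps <- function(n_sweeps, p_pre, p_post, sign = "E",
                                  group = 1L, T_max = 10, seed = 1L) {
  set.seed(seed)
  pre_hit <- which(stats::runif(n_sweeps) < p_pre)
  post_hit <- which(stats::runif(n_sweeps) < p_post)
  events <- data.frame(
    group = group, sign = sign,
    sweep = c(pre_hit, post_hit),
    rel_ms = c(stats::runif(length(pre_hit), -T_max, 0),
               stats::runif(length(post_hit), 0, T_max)),
    stringsAsFactors = FALSE)
  groups <- data.frame(sign = sign, group = group, amplitude_pA = NA_real_,
                       amplitude_sd = NA_real_, n_sweeps = n_sweeps,
                       stringsAsFactors = FALSE)
  structure(list(events = events, groups = groups, T_max = T_max),
            class = "triggered_sweeps")
}

# Brute-force parametric detection oracle: explicit binomial-CDF summation,
# no shared code with parametric_detection().
brute_force_detection <- function(p_pre, p_post, n, sign, alpha = 0.05) {
  cdf_pre <- cumsum(stats::dbinom(0:n, n, p_pre))
  if (sign == "E") {
    q <- (0:n)[match(TRUE, cdf_pre >= 1 - alpha)]
    sum(stats::dbinom(0:n, n, p_post)[(0:n) > q])
  } else {
    q <- (0:n)[match(TRUE, cdf_pre >= alpha)]
    sum(stats::dbinom(0:n, n, p_post)[(0:n) < q])
  }
}
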