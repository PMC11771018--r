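# Influence-function machinery for IPCW functionals.
#
# An IPCW estimator built from Kaplan-Meier censoring weights has, per
# subject, a first-order contribution from the weighted summand plus a
# martingale term from estimating the censoring survival G.  For a
# functional whose weights evaluate G at points u_j with coefficients c_j,
# the G-term for subject i is sum_j c_j * l_i(u_j), where
#   l_i(u) = integral over (s, u] of dM_i^c(v) / pi(v)
# is the iid expansion of -log Ghat(u|s), with M_i^c the censoring-process
# martingale and pi(v) the at-risk probability in the landmark subsample.
# The builder below precomputes the censoring-hazard structure once and then
# evaluates arbitrary weighted sums of l_i(.) in O(n log n).

# times, is_cens: observed times and censoring indicators of the landmark
# subsample (all times > s).  Returns function(u, cc, open) -> n-vector of
# sum_j cc_j l_i(u_j); open_j = TRUE evaluates the left limit l_i(u_j-).
.cens_if_builder <- function(times, is_cens) {
  ns <- length(times)
  ot <- sort(times)
  if (!any(is_cens)) {
    return(function(u, cc, open) numeric(ns))
  }
  vc <- sort(unique(times[is_cens]))
  dNc <- as.numeric(tabulate(match(times[is_cens], vc), nbins = length(vc)))
  Y <- ns - findInterval(vc, ot, left.open = TRUE)       # #{times >= v}
  qt <- ns * dNc / Y^2

  function(u, cc, open) {
    keep <- cc != 0
    u <- u[keep]; cc <- cc[keep]; open <- open[keep]
    if (!length(u)) return(numeric(ns))
    # R(v) = sum of cc_j with u_j >= v (closed) or u_j > v (open)
    ocl <- order(u)
    us <- u[ocl]; cs <- cc[ocl]; ops <- open[ocl]
    cum <- cumsum(cs)
    tot <- cum[length(cum)]
    Rv <- function(v) {
      # contributions with u < v never count; with u > v always count;
      # at u == v only closed queries count
      below_strict <- findInterval(v, us, left.open = TRUE)
      upto <- findInterval(v, us)
      base <- tot - c(0, cum)[upto + 1L]                 # strictly above v
      # add closed queries tied at v
      if (any(!ops)) {
        cls <- cumsum(cs * !ops)
        base <- base + (c(0, cls)[upto + 1L] - c(0, cls)[below_strict + 1L])
      }
      base
    }
    Rvc <- Rv(vc)
    pref <- cumsum(qt * Rvc)
    term2 <- c(0, pref)[findInterval(times, vc) + 1L]
    term1 <- numeric(ns)
    ci <- which(is_cens)
    Yi <- ns - findInterval(times[ci], ot, left.open = TRUE)
    term1[ci] <- ns / Yi * Rv(times[ci])
    term1 - term2
  }
}

# Conditional Kaplan-Meier censoring survival on a landmark subsample.
# Returns evaluators G(t) and G(t-) as closures over the product-limit.
.cens_km_eval <- function(times, is_cens) {
  if (!any(is_cens)) {
    return(list(at = function(t) rep(1, length(t)),
                at_left = function(t) rep(1, length(t))))
  }
  ot <- sort(times)
  ns <- length(times)
  vc <- sort(unique(times[is_cens]))
  dNc <- as.numeric(tabulate(match(times[is_cens], vc), nbins = length(vc)))
  Y <- ns - findInterval(vc, ot, left.open = TRUE)
  G <- cumprod(1 - dNc / Y)
  list(at = function(t) c(1, G)[findInterval(t, vc) + 1L],
       at_left = function(t) c(1, G)[findInterval(t, vc, left.open = TRUE) + 1L])
}
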