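# Internal engine: exact enumeration and numeric evaluation of the event paths
# ("paths" of the generating function) of the equal-Ne unidirectional IM model
# for a 2+2 sample.
#
# A path is an ordered sequence of events -- pairwise coalescence, migration of
# a lineage from A to B (backwards in time), and the population split at the
# fixed scaled time T -- from the initial configuration (two a-lineages in A,
# two b-lineages in B) to the MRCA. Between events the process waits in a state
# with total exit rate Lambda = (#pairs coalescing) + (#lineages in A) * M, in
# coalescent units (pair coalescence rate 1, time in 2Ne generations).
#
# For one path with pre-split states i = 1..j+1 (the last being the state in
# which the split interrupts the wait) the transform of the joint branch-length
# distribution restricted to that path is
#
#   G(omega) = prod_i r_i * I(c_1..c_{j+1}; T) * prod_k r_k / (C_k + u_k),
#
# where c_i = Lambda_i + u_i, u is the omega-weighted count of extant branches
# by type in that interval, I(c; T) is the integral of prod exp(-c_i d_i) over
# interval durations d >= 0 with fixed total T, and the trailing product runs
# over the panmictic (post-split) intervals with C_k = choose(n_k, 2).
#
# Two exact identities make expectations cheap and stable:
#   * I(c; T) = [expm(T * B)]_{1,m} with B upper-bidiagonal (-c on the
#     diagonal, 1 on the superdiagonal) -- a phase-type evaluation that is
#     robust to equal or nearly equal rates (Matrix::expm does the work);
#   * d/dc_i I(c; T) = -I(c with c_i duplicated; T), because splitting an
#     interval in two at the same rate multiplies the integrand by d_i.
# Branch-length expectations are therefore sums of duplicated-node integrals,
# with no symbolic algebra and no finite differences.

# branch type of a lineage from its leaf composition, on the unrooted 4-leaf
# genealogy (a branch is labelled by the smaller of {descendants, complement})
branch_type <- function(na, nb) {
  if (na + nb >= 4) return(NA_character_)
  if (na == 1 && nb == 0) return("a")
  if (na == 0 && nb == 1) return("b")
  if (na == 1 && nb == 1) return("ab")
  if ((na == 2 && nb == 0) || (na == 0 && nb == 2)) return("aa")
  if (na == 2 && nb == 1) return("b")  # complement {b}
  if (na == 1 && nb == 2) return("a")  # complement {a}
  stop("impossible lineage composition")
}

lineage_type_counts <- function(L) {
  out <- c(a = 0, b = 0, ab = 0, aa = 0)
  for (l in L) {
    bt <- branch_type(l$na, l$nb)
    if (!is.na(bt)) out[bt] <- out[bt] + 1
  }
  out
}

# exponential events available from a pre-split state; rates are linear in M
# and stored as (rate_c0 + rate_cM * M)
pre_split_events <- function(L) {
  ev <- list()
  n <- length(L)
  pairs <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (L[[i]]$pop != L[[j]]$pop) next
      k1 <- paste0(L[[i]]$na, "_", L[[i]]$nb)
      k2 <- paste0(L[[j]]$na, "_", L[[j]]$nb)
      ks <- sort(c(k1, k2))
      key <- paste(ks[1], ks[2], L[[i]]$pop, sep = "|")
      if (is.null(pairs[[key]])) pairs[[key]] <- list(count = 0L, i = i, j = j)
      pairs[[key]]$count <- pairs[[key]]$count + 1L
    }
  }
  for (key in names(pairs)) {
    p <- pairs[[key]]
    newlin <- list(na = L[[p$i]]$na + L[[p$j]]$na,
                   nb = L[[p$i]]$nb + L[[p$j]]$nb, pop = L[[p$i]]$pop)
    newL <- L[-c(p$i, p$j)]
    newL[[length(newL) + 1L]] <- newlin
    ev[[length(ev) + 1L]] <- list(rate_c0 = p$count, rate_cM = 0,
                                  state = newL, label = paste0("coal(", key, ")"))
  }
  migs <- list()
  for (i in seq_along(L)) {
    if (L[[i]]$pop != "A") next
    key <- paste0(L[[i]]$na, "_", L[[i]]$nb)
    if (is.null(migs[[key]])) migs[[key]] <- list(count = 0L, i = i)
    migs[[key]]$count <- migs[[key]]$count + 1L
  }
  for (key in names(migs)) {
    m <- migs[[key]]
    newL <- L
    newL[[m$i]]$pop <- "B"
    ev[[length(ev) + 1L]] <- list(rate_c0 = 0, rate_cM = m$count,
                                  state = newL, label = paste0("mig(", key, ")"))
  }
  ev
}

# panmictic coalescence sequences after the split, grouped by lineage types
post_split_tails <- function(L) {
  L <- lapply(L, function(l) { l$pop <- "AB"; l })
  rec <- function(L) {
    n <- length(L)
    if (n == 1L) return(list(list(intervals = list(), labels = character(0))))
    pairs <- list()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      k1 <- paste0(L[[i]]$na, "_", L[[i]]$nb)
      k2 <- paste0(L[[j]]$na, "_", L[[j]]$nb)
      ks <- sort(c(k1, k2))
      key <- paste(ks[1], ks[2], sep = "|")
      if (is.null(pairs[[key]])) pairs[[key]] <- list(count = 0L, i = i, j = j)
      pairs[[key]]$count <- pairs[[key]]$count + 1L
    }
    out <- list()
    CC <- n * (n - 1) / 2
    tc <- lineage_type_counts(L)
    for (key in names(pairs)) {
      p <- pairs[[key]]
      newlin <- list(na = L[[p$i]]$na + L[[p$j]]$na,
                     nb = L[[p$i]]$nb + L[[p$j]]$nb, pop = "AB")
      newL <- L[-c(p$i, p$j)]
      newL[[length(newL) + 1L]] <- newlin
      for (tl in rec(newL)) {
        out[[length(out) + 1L]] <- list(
          intervals = c(list(list(C = CC, r = p$count, counts = tc)), tl$intervals),
          labels = c(paste0("coal(", key, "|AB)"), tl$labels))
      }
    }
    out
  }
  rec(L)
}

enumerate_paths_raw <- function() {
  init <- list(list(na = 1, nb = 0, pop = "A"), list(na = 1, nb = 0, pop = "A"),
               list(na = 0, nb = 1, pop = "B"), list(na = 0, nb = 1, pop = "B"))
  paths <- list()
  rec1 <- function(L, intervals, labels, n_mig) {
    evs <- pre_split_events(L)
    sr_c0 <- sum(vapply(evs, function(e) e$rate_c0, 0))
    sr_cM <- sum(vapply(evs, function(e) e$rate_cM, 0))
    tc <- lineage_type_counts(L)
    if (length(L) > 1L) {
      wait <- list(L_c0 = sr_c0, L_cM = sr_cM, counts = tc, r_c0 = NA, r_cM = NA)
      for (tl in post_split_tails(L)) {
        paths[[length(paths) + 1L]] <<- list(
          phase1 = c(intervals, list(wait)), phase2 = tl$intervals,
          labels = c(labels, "split", tl$labels), n_mig = n_mig)
      }
    } else {
      # MRCA reached before the split: trailing absorbing interval at rate 0
      wait <- list(L_c0 = 0, L_cM = 0, counts = c(a = 0, b = 0, ab = 0, aa = 0),
                   r_c0 = NA, r_cM = NA)
      paths[[length(paths) + 1L]] <<- list(
        phase1 = c(intervals, list(wait)), phase2 = list(),
        labels = labels, n_mig = n_mig)
    }
    if (length(L) > 1L) {
      for (e in evs) {
        iv <- list(L_c0 = sr_c0, L_cM = sr_cM, counts = tc,
                   r_c0 = e$rate_c0, r_cM = e$rate_cM)
        rec1(e$state, c(intervals, list(iv)), c(labels, e$label),
             n_mig + (e$rate_cM > 0))
      }
    }
  }
  rec1(init, list(), character(0), 0L)
  paths
}

# integral of prod_i exp(-c_i d_i) over d_i >= 0 with sum(d) = T, as a
# phase-type matrix exponential entry (stable for confluent rates)
simplex_integral <- function(cvec, T) {
  m <- length(cvec)
  if (m == 1L) return(exp(-cvec * T))
  B <- diag(-cvec, nrow = m)
  B[cbind(1:(m - 1), 2:m)] <- 1
  E <- Matrix::expm(Matrix::Matrix(B * T))
  as.numeric(E[1, m])
}

# probability (G), and E[tau_a * 1(path)], E[tau_b * 1(path)] under an
# exponential load `omega` on each branch type (omega = 0 gives plain values)
eval_path_term <- function(path, T, M, omega = c(a = 0, b = 0, ab = 0, aa = 0)) {
  iv1 <- path$phase1
  cvec <- vapply(iv1, function(iv) iv$L_c0 + iv$L_cM * M + sum(iv$counts * omega), 0)
  R <- 1
  for (iv in iv1) if (!is.na(iv$r_c0)) R <- R * (iv$r_c0 + iv$r_cM * M)
  I0 <- simplex_integral(cvec, T)
  D <- vapply(path$phase2, function(iv) iv$C + sum(iv$counts * omega), 0)
  r2 <- vapply(path$phase2, function(iv) iv$r, 0)
  P2 <- if (length(D)) prod(r2 / D) else 1
  n1a <- vapply(iv1, function(iv) iv$counts[["a"]], 0)
  n1b <- vapply(iv1, function(iv) iv$counts[["b"]], 0)
  n2a <- vapply(path$phase2, function(iv) iv$counts[["a"]], 0)
  n2b <- vapply(path$phase2, function(iv) iv$counts[["b"]], 0)
  dup <- vapply(seq_along(cvec), function(i)
    simplex_integral(append(cvec, cvec[i], after = i), T), 0)
  post_a <- if (length(D)) sum(n2a / D) else 0
  post_b <- if (length(D)) sum(n2b / D) else 0
  list(G = R * I0 * P2,
       Ea = R * (sum(n1a * dup) * P2 + I0 * P2 * post_a),
       Eb = R * (sum(n1b * dup) * P2 + I0 * P2 * post_b))
}

eval_all_paths <- function(paths, T, M, omega = c(a = 0, b = 0, ab = 0, aa = 0)) {
  lapply(paths, eval_path_term, T = T, M = M, omega = omega)
}

.tt_cache <- new.env(parent = emptyenv())

# cached enumeration plus topology/symmetry classification
gf_paths <- function() {
  if (!is.null(.tt_cache$paths)) return(.tt_cache$paths)
  paths <- enumerate_paths_raw()
  incon <- vapply(paths, function(p) {
    any(vapply(p$phase1, function(iv) iv$counts[["ab"]] > 0, TRUE)) ||
      any(vapply(p$phase2, function(iv) iv$counts[["ab"]] > 0, TRUE))
  }, TRUE)
  # symmetry classification at two generic reference points: a path is
  # symmetric when its conditional a and b expectations agree identically;
  # non-symmetric paths pair up (equal probability, combined a and b lengths
  # equal -- members differ only in the order of the last two coalescences);
  # the remainder are the asymmetric paths (probability 0 at M = 0)
  refs <- list(c(0.7, 1.3), c(1.9, 0.61))
  ev <- lapply(refs, function(p) eval_all_paths(paths, p[1], p[2]))
  symmetry <- rep(NA_character_, length(paths))
  is_sym <- function(i) {
    all(vapply(ev, function(e)
      abs(e[[i]]$Ea - e[[i]]$Eb) < 1e-9 * (e[[i]]$Ea + e[[i]]$Eb), TRUE))
  }
  idx <- which(incon)
  for (i in idx) if (is_sym(i)) symmetry[i] <- "symmetric"
  nonsym <- idx[is.na(symmetry[idx])]
  pair_of <- rep(NA_integer_, length(paths))
  for (i in nonsym) {
    if (!is.na(symmetry[i])) next
    for (j in nonsym[nonsym > i]) {
      if (!is.na(symmetry[j])) next
      ok <- all(vapply(ev, function(e) {
        same_p <- abs(e[[i]]$G - e[[j]]$G) < 1e-9 * e[[i]]$G
        comb_a <- e[[i]]$Ea + e[[j]]$Ea
        comb_b <- e[[i]]$Eb + e[[j]]$Eb
        same_p && abs(comb_a - comb_b) < 1e-9 * comb_a
      }, TRUE))
      if (ok) {
        symmetry[c(i, j)] <- "paired"
        pair_of[i] <- j; pair_of[j] <- i
        break
      }
    }
    if (is.na(symmetry[i])) symmetry[i] <- "asymmetric"
  }
  out <- list(paths = paths, incongruent = incon, symmetry = symmetry,
              pair_of = pair_of)
  .tt_cache$paths <- out
  out
}
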