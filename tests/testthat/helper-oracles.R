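# Independent oracles used to validate the LP/MILP machinery, plus small
# model builders shared across test files. The oracles deliberately avoid
# the code paths they check: FBA optima are recomputed by brute-force
# vertex enumeration of the flux polytope, and loopless FVA by exhaustive
# sign-pattern enumeration with a potential-feasibility check.

# Enumerate all vertices of {v : S v = 0, lb <= v <= ub} and return the
# optimal objective for c'v. Exponential; only for n <= ~10.
vertex_fba_oracle <- function(S, obj, lb, ub, maximize = TRUE) {
  S <- as.matrix(S)
  n <- ncol(S)
  qs <- qr(t(S))
  r <- qs$rank
  rows <- if (r > 0) qs$pivot[seq_len(r)] else integer(0)
  Sr <- S[rows, , drop = FALSE]
  best <- NULL
  consider <- function(x) {
    if (any(x < lb - 1e-8) || any(x > ub + 1e-8)) return()
    val <- sum(obj * x)
    if (is.null(best) || (maximize && val > best) || (!maximize && val < best)) {
      best <<- val
    }
  }
  if (r == 0) {
    x <- ifelse((obj > 0) == maximize, ub, lb)
    consider(pmin(pmax(x, lb), ub))
    return(best)
  }
  basics <- utils::combn(n, r, simplify = FALSE)
  for (B in basics) {
    SB <- Sr[, B, drop = FALSE]
    if (abs(det(SB)) < 1e-10) next
    FF <- setdiff(seq_len(n), B)
    nf <- length(FF)
    for (mask in 0:(2^nf - 1)) {
      xf <- numeric(nf)
      for (k in seq_len(nf)) {
        at_ub <- bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0
        xf[k] <- if (at_ub) ub[FF[k]] else lb[FF[k]]
      }
      if (any(!is.finite(xf))) next
      rhs <- -if (nf > 0) as.vector(Sr[, FF, drop = FALSE] %*% xf) else rep(0, r)
      xb <- tryCatch(solve(SB, rhs), error = function(e) NULL)
      if (is.null(xb)) next
      x <- numeric(n); x[B] <- xb; x[FF] <- xf
      consider(x)
    }
  }
  best
}

# Build a gem_model directly from a stoichiometric matrix (formulas and
# names are irrelevant for pure LP checks).
model_from_matrix <- function(S, lb, ub, objective = ncol(S)) {
  S <- as.matrix(S)
  mids <- paste0("m", seq_len(nrow(S)), "_c")
  rids <- paste0("r", seq_len(ncol(S)))
  mets <- lapply(mids, function(id) met_spec(id, formula = "C", charge = 0L))
  rxns <- lapply(seq_len(ncol(S)), function(j) {
    st <- S[, j]; st <- st[st != 0]
    names(st) <- mids[S[, j] != 0]
    rxn_spec(rids[j], st, lb = lb[j], ub = ub[j])
  })
  gem_model("lp_test", mets, rxns, objective = rids[objective],
            validate = FALSE)
}

# Random small FBA-like instance with zero always feasible.
random_fba_instance <- function(seed) {
  set.seed(seed)
  m <- sample(2:4, 1); n <- sample((m + 1):8, 1)
  S <- matrix(sample(c(-2, -1, -1, 0, 0, 0, 1, 1, 2), m * n, replace = TRUE),
              m, n)
  lb <- ifelse(stats::runif(n) < 0.3, 0, -stats::runif(n, 1, 20))
  ub <- stats::runif(n, 1, 20)
  obj <- sample(seq_len(n), 1)
  list(S = S, lb = lb, ub = ub, obj = obj)
}

# Exhaustive loopless-FVA oracle: enumerate direction patterns of the
# loop-capable internal reactions; a pattern is thermodynamically
# admissible iff a potential vector G exists with sign(G) opposite the
# pattern and G orthogonal to the internal nullspace. For each admissible
# pattern run a plain sign-restricted FVA and aggregate.
oracle_loopless_range <- function(model, reaction_id) {
  S <- build_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  internal <- which(is_internal_reaction(model))
  Si <- as.matrix(S[, internal, drop = FALSE])
  V <- svd(Si, nu = 0, nv = ncol(Si))$v
  d <- svd(Si)$d
  tolr <- max(dim(Si)) * max(d, 0) * .Machine$double.eps * 100
  nullity <- ncol(Si) - sum(d > tolr)
  j <- match(reaction_id, model$reactions$id)
  plain_range <- function(lbx, ubx) {
    obj <- numeric(ncol(S)); obj[j] <- 1
    lo <- gemfba:::lp_simplex(obj, S, rep(0, nrow(S)), lbx, ubx, maximize = FALSE)
    hi <- gemfba:::lp_simplex(obj, S, rep(0, nrow(S)), lbx, ubx, maximize = TRUE)
    if (lo$status != "optimal") return(NULL)
    c(lo$objective, hi$objective)
  }
  if (nullity == 0) return(plain_range(lb, ub))
  N <- V[, seq.int(ncol(Si) - nullity + 1L, ncol(Si)), drop = FALSE]
  looped_local <- which(apply(abs(N) > 1e-9, 1, any))
  L <- internal[looped_local]
  Nl <- N[looped_local, , drop = FALSE]
  k <- length(L)
  admissible <- function(sig) {
    # feasibility of {G : sig_i * G_i <= -1, Nl' G = 0} via LP
    M <- 1000
    res <- gemfba:::lp_solve(
      obj = rep(0, k),
      Aeq = t(Nl), beq = rep(0, ncol(Nl)),
      Aub = diag(sig, k), bub = rep(-1, k),
      lb = rep(-M, k), ub = rep(M, k), maximize = TRUE)
    res$status == "optimal"
  }
  lo <- Inf; hi <- -Inf
  for (mask in 0:(2^k - 1)) {
    sig <- ifelse(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0, 1, -1)
    if (!admissible(sig)) next
    lbx <- lb; ubx <- ub
    for (t in seq_len(k)) {
      if (sig[t] > 0) lbx[L[t]] <- max(lbx[L[t]], 0) else
                      ubx[L[t]] <- min(ubx[L[t]], 0)
    }
    if (any(lbx > ubx)) next
    rng <- plain_range(lbx, ubx)
    if (is.null(rng)) next
    lo <- min(lo, rng[1]); hi <- max(hi, rng[2])
  }
  c(lo, hi)
}

# Glutamate-core test fixture with the sink added (used in several files).
core_with_sink <- function() {
  add_sink(make_glutamate_core(), "glu__L_c")
}
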