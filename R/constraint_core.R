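#' Build the stoichiometric matrix of a model
#'
#' Sparse metabolites-by-reactions matrix with signed coefficients
#' (negative = consumed). Row and column order follow model order, so the
#' representation is deterministic.
#'
#' @param model a `gem_model`.
#' @return a `dgCMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
build_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rids)) {
    st <- model$stoichiometry[[j]]
    if (length(st) == 0L) next
    ii <- c(ii, match(names(st), mids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mids), length(rids)),
                       dimnames = list(mids, rids))
}

lp_solution <- function(status, objective, fluxes) {
  structure(list(status = status, objective = objective, fluxes = fluxes),
            class = "lp_solution")
}

#' @export
print.lp_solution <- function(x, ...) {
  cat("<lp_solution> status: ", x$status,
      if (x$status == "optimal") sprintf("  objective: %.6g", x$objective),
      "\n", sep = "")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximises (or minimises) the flux through a target reaction subject to
#' the steady-state constraint `S v = 0` and the reaction bounds. The
#' optimal objective value is unique; the accompanying flux vector is one
#' optimal vertex and is *not* unique in general (alternative optima are a
#' standard feature of FBA solutions).
#'
#' @param model a `gem_model`.
#' @param objective_id reaction to optimise; defaults to the model objective
#'   (the biomass reaction, whose flux is the growth rate).
#' @param sense `"max"` or `"min"`.
#' @return an `lp_solution`: `status` ("optimal", "infeasible",
#'   "unbounded"), `objective`, and `fluxes` (named vector, mmol/gDW/h).
#'   Infeasibility and unboundedness are reported in `status`, never as
#'   errors.
#' @export
fba <- function(model, objective_id = model$objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (is.na(objective_id)) stop("no objective reaction given", call. = FALSE)
  i <- rxn_index(model, objective_id)
  S <- build_matrix(model)
  n <- ncol(S)
  obj <- numeric(n); obj[i] <- 1
  res <- lp_simplex(obj, S, rep(0, nrow(S)),
                    model$reactions$lower_bound, model$reactions$upper_bound,
                    maximize = (sense == "max"))
  fl <- if (res$status == "optimal") {
    stats::setNames(res$x, model$reactions$id)
  } else {
    stats::setNames(rep(NA_real_, n), model$reactions$id)
  }
  lp_solution(res$status, res$objective, fl)
}

#' Fix the flux of a reaction to a value
#'
#' Sets both bounds to `value`, e.g. pinning growth to 0.4 mmol/gDW/h while
#' another objective is optimised. The input model is not modified.
#'
#' @param model a `gem_model`.
#' @param reaction_id reaction to fix.
#' @param value flux value; must lie within the reaction's current bounds.
#' @return a constrained copy of the model.
#' @export
fix_flux <- function(model, reaction_id, value) {
  i <- rxn_index(model, reaction_id)
  lb <- model$reactions$lower_bound[i]
  ub <- model$reactions$upper_bound[i]
  if (value < lb - 1e-9 || value > ub + 1e-9) {
    stop("cannot fix '", reaction_id, "' to ", value,
         ": outside current bounds [", lb, ", ", ub, "]", call. = FALSE)
  }
  set_bounds(model, reaction_id, lb = value, ub = value)
}

#' Knock out a reaction or a gene
#'
#' Reaction knock-out closes both bounds to zero. Gene knock-out evaluates
#' every GPR rule with the gene deleted (`and` = all subunits required,
#' `or` = any isozyme suffices) and closes every reaction whose rule
#' evaluates false.
#'
#' @param model a `gem_model`.
#' @param target a reaction id or a gene id.
#' @return the constrained model copy.
#' @export
knockout <- function(model, target) {
  if (target %in% model$reactions$id) {
    return(set_bounds(model, target, lb = 0, ub = 0))
  }
  if (target %in% model$genes$id) {
    for (i in seq_len(nrow(model$reactions))) {
      tree <- parse_gpr(model$reactions$gpr[i])
      if (!is.null(tree) && !eval_gpr(tree, knocked = target)) {
        model$reactions$lower_bound[i] <- 0
        model$reactions$upper_bound[i] <- 0
      }
    }
    return(model)
  }
  stop("unknown knockout target '", target, "' (neither reaction nor gene)",
       call. = FALSE)
}

#' Flux variability analysis
#'
#' Sequentially minimises and maximises each requested reaction over the
#' feasible region (any prior objective fixing must already be encoded in
#' the bounds, e.g. via [fix_flux()]). With `loopless = TRUE` the feasible
#' region is additionally restricted by the thermodynamic loop law, which
#' forbids flux around internal cycles: binary direction indicators for
#' every loop-capable internal reaction are coupled to pseudo-potential
#' variables that must be orthogonal to the internal-reaction nullspace
#' (solved exactly as a small mixed-integer program).
#'
#' @param model a `gem_model`.
#' @param reaction_ids reactions to analyse (default: all).
#' @param loopless apply the loop law.
#' @return data.frame with columns `id`, `min`, `max` (mmol/gDW/h).
#' @export
fva <- function(model, reaction_ids = model$reactions$id, loopless = FALSE) {
  idx <- rxn_index(model, reaction_ids)
  S <- build_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  feas <- lp_simplex(numeric(ncol(S)), S, rep(0, nrow(S)), lb, ub)
  if (feas$status != "optimal") {
    stop("model is infeasible under the current constraints", call. = FALSE)
  }
  ll <- if (loopless) loopless_system(model, S) else NULL
  res <- lapply(idx, function(i) {
    if (loopless && !is.null(ll)) {
      lo <- loopless_opt(ll, i, maximize = FALSE)
      hi <- loopless_opt(ll, i, maximize = TRUE)
    } else {
      obj <- numeric(ncol(S)); obj[i] <- 1
      lo <- lp_simplex(obj, S, rep(0, nrow(S)), lb, ub, maximize = FALSE)
      hi <- lp_simplex(obj, S, rep(0, nrow(S)), lb, ub, maximize = TRUE)
    }
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem for '", model$reactions$id[i], "' returned ",
           lo$status, "/", hi$status, call. = FALSE)
    }
    c(lo$objective, hi$objective)
  })
  out <- data.frame(id = model$reactions$id[idx],
                    min = vapply(res, `[`, 0, 1),
                    max = vapply(res, `[`, 0, 2),
                    stringsAsFactors = FALSE)
  # clamp the tiny numerical inversions a pair of LPs can produce
  sw <- out$min > out$max
  if (any(sw)) {
    m <- (out$min[sw] + out$max[sw]) / 2
    out$min[sw] <- m; out$max[sw] <- m
  }
  rownames(out) <- NULL
  out
}

# Assemble the loop-law MILP scaffolding once per model.
#
# Variables are ordered [v (n), a (k), G (k)] where k indexes the
# loop-capable internal reactions: internal reactions with non-zero entries
# in a basis of the nullspace of S restricted to internal columns. a_j = 1
# encodes forward flux (v >= 0) and forces G_j <= -1; a_j = 0 encodes
# backward flux and G_j >= 1; N' G = 0 closes the loop law. Big-M = 1000
# matches the default bound magnitude.
loopless_system <- function(model, S = build_matrix(model), M = 1000) {
  internal <- which(is_internal_reaction(model))
  n <- ncol(S)
  if (length(internal) == 0L) return(NULL)
  Si <- as.matrix(S[, internal, drop = FALSE])
  sv <- svd(Si, nu = 0, nv = min(dim(Si)[2], nrow(Si) + ncol(Si)))
  d <- sv$d
  tolr <- max(dim(Si)) * max(d, 0) * .Machine$double.eps * 100
  nullity <- ncol(Si) - sum(d > tolr)
  if (nullity == 0L) return(NULL)
  V <- svd(Si, nu = 0, nv = ncol(Si))$v
  N <- V[, seq.int(ncol(Si) - nullity + 1L, ncol(Si)), drop = FALSE]
  looped_local <- which(apply(abs(N) > 1e-9, 1, any))
  if (length(looped_local) == 0L) return(NULL)
  looped <- internal[looped_local]
  Nl <- N[looped_local, , drop = FALSE]
  k <- length(looped)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound

  ntot <- n + 2L * k
  # equality rows: steady state + nullspace orthogonality of G
  Aeq <- matrix(0, nrow(S) + ncol(Nl), ntot)
  Aeq[seq_len(nrow(S)), seq_len(n)] <- as.matrix(S)
  Aeq[nrow(S) + seq_len(ncol(Nl)), n + k + seq_len(k)] <- t(Nl)
  beq <- rep(0, nrow(Aeq))
  # inequality rows per looped reaction
  Aub <- matrix(0, 4L * k, ntot)
  bub <- numeric(4L * k)
  for (j in seq_len(k)) {
    r <- looped[j]; av <- n + j; gv <- n + k + j
    row <- 4L * (j - 1L)
    Aub[row + 1L, r] <- 1;  Aub[row + 1L, av] <- -ub[r];      bub[row + 1L] <- 0
    Aub[row + 2L, r] <- -1; Aub[row + 2L, av] <- -lb[r];      bub[row + 2L] <- -lb[r]
    Aub[row + 3L, gv] <- 1;  Aub[row + 3L, av] <- M + 1;      bub[row + 3L] <- M
    Aub[row + 4L, gv] <- -1; Aub[row + 4L, av] <- -(M + 1);   bub[row + 4L] <- -1
  }
  list(Aeq = Aeq, beq = beq, Aub = Aub, bub = bub,
       lb = c(lb, rep(0, k), rep(-M, k)),
       ub = c(ub, rep(1, k), rep(M, k)),
       n = n, int_idx = n + seq_len(k), looped = looped)
}

loopless_opt <- function(ll, target, maximize) {
  obj <- numeric(length(ll$lb)); obj[target] <- 1
  res <- milp_solve(obj, ll$Aeq, ll$beq, ll$Aub, ll$bub, ll$lb, ll$ub,
                    int_idx = ll$int_idx, maximize = maximize)
  res
}
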