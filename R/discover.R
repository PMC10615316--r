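# Implicit sparse regression (SINDy-PI style) for rational ODE discovery.

#' Logarithmic threshold grid
#' @param n number of values.
#' @param from,to range (default 1e-4 .. 1).
#' @return numeric vector.
#' @export
lambda_grid <- function(n = 20, from = 1e-4, to = 1) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Sequentially thresholded least squares
#'
#' Alternates a least-squares fit on the active columns with hard
#' thresholding of coefficients smaller in magnitude than `lam`, until the
#' active set is stable. Returned coefficients contain exact zeros.
#'
#' @param A m x k design matrix.
#' @param b m response vector.
#' @param lam threshold (>= 0); `lam = 0` gives ordinary least squares.
#' @return coefficient vector of length k; attribute `all_zero` is TRUE when
#'   thresholding eliminated every column.
#' @export
stlsq <- function(A, b, lam) {
  if (lam < 0) stop("lam must be >= 0")
  k <- ncol(A)
  active <- rep(TRUE, k)
  xi <- numeric(k)
  ls_fit <- function(cols) {
    qrA <- qr(A[, cols, drop = FALSE])
    cf <- qr.coef(qrA, b)
    if (anyNA(cf)) {
      warning("rank-deficient active set in stlsq; aliased columns zeroed")
      cf[is.na(cf)] <- 0
    }
    cf
  }
  for (it in seq_len(k + 1)) {
    if (!any(active)) break
    cf <- ls_fit(active)
    xi[] <- 0
    xi[active] <- cf
    drop_ <- active & (abs(xi) < lam)
    if (!any(drop_)) break
    active <- active & !drop_
  }
  if (!any(active)) xi[] <- 0
  structure(xi, all_zero = !any(active & xi != 0))
}

#' Sweep library terms and thresholds
#'
#' For every admissible left-hand-side term (a term containing the derivative
#' symbol) and every threshold in `lambdas`, regress that term on the rest of
#' the library with [stlsq()]. Columns are normalized to unit root mean
#' square before thresholding (so thresholds are comparable across monomial
#' degrees) and coefficients rescaled afterwards. All-zero fits are dropped.
#'
#' @param library a `function_library`.
#' @param data a `ts_data`.
#' @param lambdas threshold grid.
#' @return list of sparse fits: each has `lhs` (term index), `xi` (length
#'   |terms|, zero at `lhs`), `lambda`, `rss`, `complexity`.
#' @export
sweep_candidates <- function(library, data, lambdas = lambda_grid()) {
  Theta <- evaluate_library(library, data)
  nm <- library$n_mono
  lhs_candidates <- nm + seq_len(nm)  # terms containing the derivative
  rms <- sqrt(colMeans(Theta^2))
  rms[rms < 1e-300] <- 1
  fits <- list()
  n_rankdef <- 0
  for (j in lhs_candidates) {
    b <- Theta[, j]
    brms <- sqrt(mean(b^2))
    if (brms < 1e-300) next
    A <- Theta[, -j, drop = FALSE] / rep(rms[-j], each = nrow(Theta))
    bs <- b / brms
    for (lam in lambdas) {
      xi_s <- withCallingHandlers(
        stlsq(A, bs, lam),
        warning = function(w) {
          n_rankdef <<- n_rankdef + 1
          invokeRestart("muffleWarning")
        })
      if (attr(xi_s, "all_zero")) next
      xi <- numeric(ncol(Theta))
      xi[-j] <- xi_s * brms / rms[-j]
      res <- b - Theta[, -j, drop = FALSE] %*% xi[-j]
      fits[[length(fits) + 1]] <-
        list(lhs = j, xi = xi, lambda = lam,
             rss = sum(res^2),
             complexity = sum(xi != 0) + 1)
    }
  }
  if (n_rankdef > 0)
    warning(n_rankdef, " rank-deficient STLSQ fit(s) in sweep; ",
            "aliased columns zeroed")
  if (!length(fits)) return(structure(list(), no_candidate = TRUE))
  # deduplicate identical supports per lhs (different lambdas often agree)
  sig <- vapply(fits, function(f)
    paste(f$lhs, paste(which(f$xi != 0), collapse = ","),
          paste(signif(f$xi[f$xi != 0], 8), collapse = ","), sep = "|"),
    character(1))
  fits[!duplicated(sig)]
}

#' Solve an implicit fit for the state derivative
#'
#' The implicit equation `theta_j = sum_i xi_i theta_i` is linear in the
#' derivative symbol; collecting its terms on the left gives
#' `dx * D(x) = N(x)`, hence the explicit rational right-hand side
#' `dx/dt = N(x) / D(x)`.
#'
#' @param fit a sparse fit from [sweep_candidates()].
#' @param library the `function_library` it was fitted against.
#' @return list with `num`, `den` (numeric `spoly` in the states, denominator
#'   normalized to constant term 1 when possible), or an error if the
#'   derivative coefficient vanishes identically.
#' @export
assemble_explicit <- function(fit, library) {
  nm <- library$n_mono
  states <- library$states
  mkpoly <- function(idx, coefs) {
    if (!length(idx)) return(sp_zero(states))
    sp_make(states, library$E[idx, , drop = FALSE], as.list(coefs), tol = 0)
  }
  # D: monomial of the lhs term minus fitted derivative-block terms
  d_idx <- which(fit$xi[nm + seq_len(nm)] != 0)
  D <- sp_sub(mkpoly(fit$lhs - nm, list(1)),
              mkpoly(d_idx, fit$xi[nm + d_idx]))
  N <- mkpoly(which(fit$xi[seq_len(nm)] != 0),
              fit$xi[which(fit$xi[seq_len(nm)] != 0)])
  if (sp_is_zero(D)) stop("derivative coefficient vanished; no explicit form")
  # normalize denominator scale
  const_i <- which(rowSums(D$E) == 0)
  sc <- if (length(const_i)) D$cf[[const_i]] else D$cf[[sp_lead(D)]]
  if (abs(sc) > 1e-300) {
    D <- sp_scale(D, 1 / sc)
    N <- sp_scale(N, 1 / sc)
  }
  list(num = N, den = D)
}

# relative magnitude of an spoly's coefficients
.sp_scale_of <- function(p) {
  if (sp_is_zero(p)) return(0)
  max(vapply(p$cf, function(c0) abs(cf_num_value(c0)), numeric(1)))
}

sp_near_zero <- function(p, tol, scale = 1) {
  sp_is_zero(sp_norm(p, tol * max(scale, 1e-12)))
}

#' Pareto/AIC selection among assembled candidates
#'
#' Scores each candidate by its normalized derivative residual on held-out
#' validation data, discards candidates whose denominator approaches zero on
#' the training trajectories, and selects the AIC minimizer
#' (AIC = m log(RSS/m) + 2k, k = active coefficients including the
#' left-hand-side denominator terms; AICc available via `small_sample`).
#' The residual mean square is floored at the square of `rss_floor_rel`
#' times the derivative scale, so that candidates agreeing with the data to
#' within numerical precision tie and the tie-break (lower complexity, then
#' lower error) decides.
#'
#' @param candidates list of entries with `num`, `den`, `complexity`.
#' @param train,valid `ts_data` objects.
#' @param state index (column) of the state these candidates model.
#' @param small_sample use the AICc correction.
#' @param rss_floor_rel relative residual floor (default 1e-9).
#' @return index of the selected candidate, with the score table as
#'   attribute `table`.
#' @export
select_pareto <- function(candidates, train, valid, state,
                          small_sample = FALSE, rss_floor_rel = 1e-9) {
  if (!length(candidates)) stop("no candidate to select from")
  m <- length(valid$time)
  dscale <- stats::sd(valid$Xdot[, state])
  floor_ <- (rss_floor_rel * max(dscale, 1e-12))^2
  rows <- lapply(seq_along(candidates), function(i) {
    cn <- candidates[[i]]
    denv_t <- sp_eval_rows(cn$den, train$X)
    if (min(abs(denv_t)) < 1e-6 * max(abs(denv_t)) ||
        (min(denv_t) < 0 && max(denv_t) > 0))
      return(list(i = i, ok = FALSE, reason = "denominator vanishes on data"))
    denv <- sp_eval_rows(cn$den, valid$X)
    if (min(abs(denv)) < 1e-10)
      return(list(i = i, ok = FALSE, reason = "denominator vanishes on validation"))
    pred <- sp_eval_rows(cn$num, valid$X) / denv
    msr <- mean((valid$Xdot[, state] - pred)^2)
    k <- cn$complexity
    aic <- m * log(max(msr, floor_)) + 2 * k
    if (small_sample && m - k - 1 > 0) aic <- aic + 2 * k * (k + 1) / (m - k - 1)
    list(i = i, ok = TRUE, msr = msr, k = k, aic = aic,
         nmse = msr / max(mean(valid$Xdot[, state]^2), 1e-300))
  })
  ok <- Filter(function(r) r$ok, rows)
  if (!length(ok)) stop("no candidate survived the degeneracy guard")
  aics <- vapply(ok, `[[`, numeric(1), "aic")
  ks <- vapply(ok, `[[`, numeric(1), "k")
  msrs <- vapply(ok, `[[`, numeric(1), "msr")
  best <- order(round(aics, 6), ks, msrs)[1]
  structure(ok[[best]]$i, table = rows)
}

# ---- candidate-model presentation -----------------------------------------

# heuristic factorization of a numeric spoly: repeatedly try derivative
# quotients as factors (complete for products of factors that are linear in
# some variable); returns factors (each normalized to constant/leading 1)
# and the overall scalar so that D = scale * prod(factors)
sp_factor <- function(D, tol = 1e-8) {
  numeric_cf <- all(vapply(D$cf, cf_is_num, logical(1)))
  if (!numeric_cf) tol <- 0
  scale <- 1
  norm1 <- function(F) {
    ci <- which(rowSums(F$E) == 0)
    s <- if (length(ci)) F$cf[[ci]] else F$cf[[sp_lead(F)]]
    list(F = sp_scale(F, cf_div(1, s)), s = s)
  }
  rec <- function(F) {
    sc <- if (numeric_cf) .sp_scale_of(F) else 1
    if (sp_deg(F) <= 1) return(list(F))
    for (v in F$svars) {
      G <- sp_deriv(F, v)
      if (sp_is_zero(G) || sp_deg(G) < 1 || sp_deg(G) >= sp_deg(F)) next
      nG <- norm1(G)$F
      dv <- sp_divrem(F, nG)
      if (sp_near_zero(dv$r, tol, sc) && sp_deg(dv$q) >= 1) {
        return(c(rec(nG), rec(dv$q)))
      }
    }
    list(F)
  }
  parts <- rec(D)
  out <- list()
  for (F in parts) {
    n <- norm1(F)
    scale <- cf_mul(scale, n$s)
    out[[length(out) + 1]] <- n$F
  }
  list(factors = out, scale = scale)
}

# monomial supports for a proper partial-fraction numerator over factor F
.pf_support <- function(states, max_deg, F) {
  E <- monomial_exponents(length(states), max_deg)
  lt <- F$E[sp_lead(F), ]
  keep <- apply(E, 1, function(e) !all(e >= lt))
  E[keep, , drop = FALSE]
}

# decompose N/D as q + sum_k A_k / (prod of factor powers), the way the
# candidate models are conventionally printed: polynomial quotient plus one
# proper rational term per denominator factor (with multiplicity).
rational_presentation <- function(N, D, tol = 1e-8) {
  states <- N$svars
  fac <- sp_factor(D, tol)
  fscale <- cf_num_value(fac$scale)
  if (abs(fscale) > 1e-300 && abs(fscale - 1) > 0) {
    N <- sp_scale(N, 1 / fscale)
  }
  # group equal factors into powers
  groups <- list()
  for (F in fac$factors) {
    hit <- FALSE
    for (gi in seq_along(groups)) {
      if (sp_near_zero(sp_sub(groups[[gi]]$F, F), tol, .sp_scale_of(F))) {
        groups[[gi]]$mult <- groups[[gi]]$mult + 1; hit <- TRUE; break
      }
    }
    if (!hit) groups[[length(groups) + 1]] <- list(F = F, mult = 1)
  }
  Dn <- sp_const(states, 1)
  for (g in groups) for (i in seq_len(g$mult)) Dn <- sp_mul(Dn, g$F)
  degN <- sp_deg(N); degD <- sp_deg(Dn)
  if (degD == 0) {
    # purely polynomial right-hand side
    return(list(terms = list(list(type = "poly", num = N)), den = Dn,
                groups = groups, quotient = N))
  }
  # unknown blocks: quotient + one numerator per factor power; the proper
  # numerator support is tried tight (degree of the factor) first, and, when
  # the tight system is inconsistent (homogeneous denominators without a
  # constant term need higher-degree reduced monomials), with the loose
  # degree bound
  build_blocks <- function(loose) {
    blocks <- list()
    if (degN >= degD)
      blocks[[length(blocks) + 1]] <-
        list(type = "q", E = monomial_exponents(length(states), degN - degD),
             mult = Dn)
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      for (j in seq_len(g$mult)) {
        co <- sp_const(states, 1)
        for (g2i in seq_along(groups)) {
          g2 <- groups[[g2i]]
          pw <- if (g2i == gi) g2$mult - j else g2$mult
          for (t in seq_len(pw)) co <- sp_mul(co, g2$F)
        }
        bound <- if (loose) max(sp_deg(g$F), degN - sp_deg(co))
                 else sp_deg(g$F)
        blocks[[length(blocks) + 1]] <-
          list(type = "pf", E = .pf_support(states, bound, g$F),
               mult = co, gi = gi, pow = j)
      }
    }
    blocks
  }
  keyE <- function(E) apply(E, 1, paste, collapse = ",")
  solve_blocks <- function(blocks) {
    contribs <- list()
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      for (r in seq_len(nrow(b$E))) {
        mono <- sp_make(states, b$E[r, , drop = FALSE], list(1))
        pr <- sp_mul(mono, b$mult)
        contribs[[length(contribs) + 1]] <-
          list(block = bi, row = r, poly = pr)
      }
    }
    all_keys <- unique(c(unlist(lapply(contribs,
                                       function(cb) keyE(cb$poly$E))),
                         keyE(N$E)))
    Amat <- matrix(0, length(all_keys), length(contribs))
    for (ci in seq_along(contribs)) {
      pr <- contribs[[ci]]$poly
      if (sp_is_zero(pr)) next
      idx <- match(keyE(pr$E), all_keys)
      Amat[idx, ci] <- vapply(pr$cf, cf_num_value, numeric(1))
    }
    bvec <- numeric(length(all_keys))
    if (!sp_is_zero(N))
      bvec[match(keyE(N$E), all_keys)] <-
        vapply(N$cf, cf_num_value, numeric(1))
    sol <- tryCatch(qr.coef(qr(Amat, LAPACK = TRUE), bvec),
                    error = function(e) NULL)
    if (!is.null(sol)) sol[is.na(sol)] <- 0
    ok <- !is.null(sol) &&
      sqrt(sum((Amat %*% sol - bvec)^2)) <= tol * max(1, sqrt(sum(bvec^2)))
    if (!ok) return(NULL)
    sol
  }
  blocks <- build_blocks(loose = FALSE)
  sol <- solve_blocks(blocks)
  if (is.null(sol)) {
    blocks <- build_blocks(loose = TRUE)
    sol <- solve_blocks(blocks)
  }
  if (is.null(sol)) {
    # fall back to the unfactored single rational term
    return(list(terms = list(list(type = "rat", num = N, den = Dn)),
                den = Dn, groups = groups, quotient = sp_zero(states)))
  }
  # chop small coefficients relative to each block's scale and rebuild terms
  sol[abs(sol) < tol * max(1, max(abs(sol)))] <- 0
  terms <- list(); quotient <- sp_zero(states)
  pos <- 1
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    nr <- nrow(b$E)
    coefs <- sol[pos:(pos + nr - 1)]
    pos <- pos + nr
    keep <- which(coefs != 0)
    if (!length(keep)) next
    A <- sp_make(states, b$E[keep, , drop = FALSE], as.list(coefs[keep]))
    if (b$type == "q") {
      quotient <- sp_add(quotient, A)
      terms[[length(terms) + 1]] <- list(type = "poly", num = A)
    } else {
      den <- sp_const(states, 1)
      for (t in seq_len(blocks[[bi]]$pow)) den <- sp_mul(den, groups[[b$gi]]$F)
      terms[[length(terms) + 1]] <- list(type = "rat", num = A, den = den)
    }
  }
  if (!length(terms)) terms <- list(list(type = "poly", num = sp_zero(states)))
  list(terms = terms, den = Dn, groups = groups, quotient = quotient)
}

# Build the candidate ode_model from per-state presentations, assigning a
# fresh coefficient symbol to every slot (quotient monomials, rational-term
# numerator coefficients and denominator coefficients other than the leading
# normalization), the way such models are conventionally reported.
cm_from_presentations <- function(pres_list, states, name = "CM") {
  idx <- 0
  params <- character(0); values <- numeric(0)
  fresh <- function(v) {
    idx <<- idx + 1
    nm <- paste0("p", idx)
    params <<- c(params, nm)
    values <<- c(values, stats::setNames(v, nm))
    nm
  }
  mono_str <- function(E, svars) {
    s <- character(0)
    for (k in seq_along(svars)) {
      if (E[k] == 1) s <- c(s, svars[k])
      else if (E[k] > 1) s <- c(s, paste0(svars[k], "^", E[k]))
    }
    if (!length(s)) "" else paste(s, collapse = "*")
  }
  sp_param_str <- function(p, free_all = TRUE) {
    parts <- vapply(seq_len(nrow(p$E)), function(i) {
      v <- cf_num_value(p$cf[[i]])
      ms <- mono_str(p$E[i, ], p$svars)
      if (free_all || abs(v - 1) > 0) {
        nm <- fresh(v)
        if (ms == "") nm else paste0(nm, "*", ms)
      } else {
        if (ms == "") "1" else ms
      }
    }, character(1))
    paste(parts, collapse = " + ")
  }
  dyn <- character(0)
  for (si in seq_along(pres_list)) {
    pr <- pres_list[[si]]
    pieces <- character(0)
    for (tm in pr$terms) {
      if (tm$type == "poly") {
        if (sp_is_zero(tm$num)) { pieces <- c(pieces, "0"); next }
        pieces <- c(pieces, sp_param_str(tm$num))
      } else {
        ns <- sp_param_str(tm$num)
        ds <- sp_param_str(tm$den)
        pieces <- c(pieces, paste0("(", ns, ")/(", ds, ")"))
      }
    }
    dyn <- c(dyn, if (length(pieces)) paste(pieces, collapse = " + ") else "0")
  }
  ode_model(name = name, states = states, params = params, dynamics = dyn,
            param_values = values)
}

# ---- the fitting front end -------------------------------------------------

#' Discover a rational ODE model from time-series data
#'
#' Implicit sparse regression in the SINDy-PI spirit: for each state, build
#' the implicit candidate library (monomials and derivative-times-monomial
#' terms), sweep every admissible left-hand side over a logarithmic threshold
#' grid with sequentially thresholded least squares, assemble each sparse
#' implicit fit into an explicit rational right-hand side, and select the
#' candidate with the best AIC / complexity trade-off on held-out validation
#' data. The selected per-state forms are combined into a candidate model
#' whose coefficients become fresh parameters `p1, p2, ...`.
#'
#' @param data training `ts_data` (from [training_data()] or [read_ts()]).
#' @param degree library degree (single value or per-state vector).
#' @param lambdas threshold grid (default [lambda_grid()]).
#' @param validation held-out `ts_data`; defaults to a random quarter of the
#'   training trajectories when NULL.
#' @param name name for the discovered model.
#' @param small_sample use AICc instead of AIC.
#' @return an object of class `sindy_fit` with components `model` (the
#'   candidate [ode_model] with fitted values), `per_state` (selection
#'   details), `settings`.
#' @export
discover <- function(data, degree, lambdas = lambda_grid(), validation = NULL,
                     name = "CM", small_sample = FALSE) {
  states <- data$states
  if (length(degree) == 1) degree <- rep(degree, length(states))
  if (is.null(validation)) {
    tr_ids <- unique(data$traj)
    if (length(tr_ids) > 1) {
      hold <- tr_ids[seq(1, length(tr_ids), by = 4)]
      keep <- !(data$traj %in% hold)
      validation <- ts_data(data$time[!keep], data$X[!keep, , drop = FALSE],
                            data$Xdot[!keep, , drop = FALSE], states,
                            data$traj[!keep], data$provenance)
      data <- ts_data(data$time[keep], data$X[keep, , drop = FALSE],
                      data$Xdot[keep, , drop = FALSE], states,
                      data$traj[keep], data$provenance)
    } else validation <- data
  }
  per_state <- list()
  pres <- list()
  for (si in seq_along(states)) {
    lib <- build_implicit_library(states, states[si], degree[si])
    fits <- sweep_candidates(lib, data, lambdas)
    if (!length(fits)) {
      # a state with identically zero derivative has no admissible
      # left-hand side; its dynamics are the trivial zero model
      if (sqrt(mean(data$Xdot[, si]^2)) <=
          1e-10 * max(1, stats::sd(data$X[, si]))) {
        pres[[si]] <- list(terms = list(list(type = "poly",
                                             num = sp_zero(states))),
                           den = sp_const(states, 1),
                           quotient = sp_zero(states))
        per_state[[states[si]]] <-
          list(library = lib, chosen = NULL, n_candidates = 0, table = NULL)
        next
      }
      stop("no candidate found for state ", states[si])
    }
    cands <- list()
    for (f in fits) {
      asm <- tryCatch(assemble_explicit(f, lib), error = function(e) NULL)
      if (is.null(asm)) next
      cands[[length(cands) + 1]] <-
        list(num = asm$num, den = asm$den, complexity = f$complexity,
             fit = f)
    }
    if (!length(cands)) stop("no assemblable candidate for state ", states[si])
    sel <- select_pareto(cands, data, validation, si,
                         small_sample = small_sample)
    chosen <- cands[[sel]]
    pres[[si]] <- rational_presentation(chosen$num, chosen$den)
    per_state[[states[si]]] <-
      list(library = lib, chosen = chosen, n_candidates = length(cands),
           table = attr(sel, "table"))
  }
  model <- cm_from_presentations(pres, states, name = name)
  structure(list(model = model, per_state = per_state, presentations = pres,
                 settings = list(degree = degree, lambdas = lambdas),
                 data_provenance = data$provenance),
            class = "sindy_fit")
}

#' @export
print.sindy_fit <- function(x, ...) {
  cat("implicit sparse-regression fit:", length(x$model$params),
      "coefficients over", length(x$model$states), "states\n")
  print(x$model)
  invisible(x)
}

#' @export
summary.sindy_fit <- function(object, ...) {
  cat("discovered candidate model '", object$model$name, "'\n", sep = "")
  print(object$model)
  for (s in names(object$per_state)) {
    ps <- object$per_state[[s]]
    if (is.null(ps$chosen)) {
      cat(" state ", s, ": trivial zero dynamics\n", sep = "")
      next
    }
    f <- ps$chosen$fit
    cat(" state ", s, ": lhs = ", ps$library$terms[f$lhs],
        ", lambda = ", signif(f$lambda, 3),
        ", active terms = ", sum(f$xi != 0),
        ", candidates considered = ", ps$n_candidates, "\n", sep = "")
  }
  invisible(object)
}

#' @export
coef.sindy_fit <- function(object, ...) object$model$param_values

#' @export
predict.sindy_fit <- function(object, newdata, ...) {
  # derivative predictions on a ts_data or state matrix
  X <- if (inherits(newdata, "ts_data")) newdata$X else as.matrix(newdata)
  rhs <- model_rhs(object$model)
  t(apply(X, 1, function(y)
    rhs(0, stats::setNames(y, object$model$states), NULL)[[1]]))
}

#' @export
residuals.sindy_fit <- function(object, data, ...) {
  if (missing(data)) stop("supply the ts_data to compute residuals against")
  data$Xdot - predict(object, data)
}

#' @export
simulate.sindy_fit <- function(object, nsim = 1, seed = NULL, x0,
                               times = seq(0, 10, length.out = 200), ...) {
  simulate_model(object$model, x0 = x0, times = times)
}

#' @export
plot.sindy_fit <- function(x, data, ...) {
  if (missing(data)) stop("supply a ts_data to plot against")
  pred <- predict(x, data)
  n <- ncol(data$X)
  op <- graphics::par(mfrow = c(n, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(n)) {
    graphics::plot(data$time, data$Xdot[, i], pch = 16, cex = 0.4,
                   xlab = "t", ylab = paste0("d", data$states[i], "/dt"))
    graphics::points(data$time, pred[, i], col = 2, cex = 0.3)
  }
  invisible(x)
}
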