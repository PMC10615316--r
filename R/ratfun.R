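# Rational functions num/den over the exact polynomial layer, plus conversion
# between R expressions and rational-function form. Denominators are kept
# normalized: the constant term is scaled to 1 when nonzero, otherwise the
# grlex-leading coefficient is scaled to 1 (the convention used throughout for
# reparameterized and dictionary forms).

rf_make <- function(num, den = mp_const(1)) {
  if (mp_is_zero(den)) stop("rational function with zero denominator")
  r <- list(num = num, den = den)
  class(r) <- "ratfun"
  rf_norm(r)
}

rf_is_zero <- function(r) mp_is_zero(r$num)

# cancel exact polynomial divisibility and common monomial content, then
# normalize the denominator scale
rf_norm <- function(r) {
  num <- r$num; den <- r$den
  if (mp_is_zero(num)) {
    r$num <- num; r$den <- mp_const(1)
    return(r)
  }
  # common monomial/numeric content
  cn <- mp_content(num); cdn <- mp_content(den)
  # monomial part: cancel min exponents
  both <- .mp_align(cn$content, cdn$content)
  e <- pmin(both$a$E[1, ], both$b$E[1, ])
  if (any(e > 0)) {
    strip <- function(p, e, vars) {
      E <- p$E
      for (k in seq_along(vars)) {
        j <- match(vars[k], p$vars)
        if (!is.na(j)) E[, j] <- E[, j] - e[k]
      }
      mp_make(p$vars, E, p$cn, p$cd)
    }
    num <- strip(num, e, both$vars)
    den <- strip(den, e, both$vars)
  }
  # exact polynomial cancellation
  if (mp_total_deg(den) > 0 && mp_total_deg(num) >= mp_total_deg(den)) {
    dv <- mp_divrem(num, den)
    if (mp_is_zero(dv$r)) { num <- dv$q; den <- mp_const(1) }
  }
  if (mp_total_deg(den) > 0 && mp_total_deg(num) > 0 &&
      mp_total_deg(num) <= mp_total_deg(den)) {
    dv <- mp_divrem(den, num)
    if (mp_is_zero(dv$r) && !mp_is_zero(dv$q)) { den <- dv$q; num <- mp_const(1) }
  }
  # factor-wise cancellation keeps iterated quotient-rule denominators at
  # their minimal power (essential for Lie derivatives of rational models)
  if (mp_total_deg(den) >= 2 && nrow(den$E) <= 400) {
    fs <- tryCatch(mp_factor(den), error = function(e) list())
    seen <- character(0)
    for (f in fs) {
      if (mp_total_deg(f) < 1) next
      key <- mp_to_string(f)
      if (key %in% seen) next
      seen <- c(seen, key)
      repeat {
        dvn <- tryCatch(mp_divrem(num, f), error = function(e) NULL)
        if (is.null(dvn) || !mp_is_zero(dvn$r)) break
        dvd <- mp_divrem(den, f)
        if (!mp_is_zero(dvd$r)) break
        num <- dvn$q; den <- dvd$q
      }
    }
  }
  # scale: denominator constant term -> 1 (or leading coefficient -> 1)
  const_idx <- which(rowSums(den$E) == 0)
  i <- if (length(const_idx)) const_idx else mp_lead(den)
  num <- mp_scale(num, den$cd[i], den$cn[i])
  den <- mp_scale(den, den$cd[i], den$cn[i])
  r$num <- num; r$den <- den
  r
}

rf_const <- function(num, den = 1) rf_make(mp_const(num, den))
rf_var <- function(v) rf_make(mp_var(v))

rf_add <- function(a, b) {
  same_den <- mp_equal(a$den, b$den)
  if (same_den) return(rf_make(mp_add(a$num, b$num), a$den))
  rf_make(mp_add(mp_mul(a$num, b$den), mp_mul(b$num, a$den)),
          mp_mul(a$den, b$den))
}

rf_neg <- function(a) { a$num <- mp_neg(a$num); a }
rf_sub <- function(a, b) rf_add(a, rf_neg(b))

rf_mul <- function(a, b) {
  # cross-cancel before multiplying to keep things small
  r1 <- rf_make(a$num, b$den)
  r2 <- rf_make(b$num, a$den)
  rf_make(mp_mul(r1$num, r2$num), mp_mul(r1$den, r2$den))
}

rf_div <- function(a, b) {
  if (rf_is_zero(b)) stop("division by zero rational function")
  rf_mul(a, rf_make(b$den, b$num))
}

rf_pow <- function(a, k) {
  k <- as.integer(k)
  if (k < 0) return(rf_pow(rf_make(a$den, a$num), -k))
  rf_make(mp_pow(a$num, k), mp_pow(a$den, k))
}

rf_deriv <- function(a, v) {
  n1 <- mp_mul(mp_deriv(a$num, v), a$den)
  n2 <- mp_mul(a$num, mp_deriv(a$den, v))
  rf_make(mp_sub(n1, n2), mp_mul(a$den, a$den))
}

rf_subs <- function(a, v, repl_rf) {
  # substitute a rational function for a variable
  sub_poly <- function(p) {
    j <- match(v, p$vars)
    if (is.na(j)) return(rf_make(p))
    out <- rf_const(0)
    for (i in seq_len(nrow(p$E))) {
      term <- rf_const(p$cn[i], p$cd[i])
      for (k in seq_along(p$vars)) {
        e <- p$E[i, k]
        if (e == 0) next
        f <- if (k == j) rf_pow(repl_rf, e) else rf_make(mp_var(p$vars[k], e))
        term <- rf_mul(term, f)
      }
      out <- rf_add(out, term)
    }
    out
  }
  rf_div(sub_poly(a$num), sub_poly(a$den))
}

rf_equal <- function(a, b) {
  mp_is_zero(mp_sub(mp_mul(a$num, b$den), mp_mul(b$num, a$den)))
}

rf_eval_num <- function(a, env) mp_eval_num(a$num, env) / mp_eval_num(a$den, env)

rf_to_string <- function(a) {
  ns <- mp_to_string(a$num)
  if (mp_total_deg(a$den) == 0 && mp_equal(a$den, mp_const(1))) return(ns)
  ds <- mp_to_string(a$den)
  nwrap <- if (nrow(a$num$E) > 1) paste0("(", ns, ")") else ns
  paste0(nwrap, "/(", ds, ")")
}

# ---- R expression -> rational function ------------------------------------

# Parse a conventional infix expression (call/symbol/numeric) into a ratfun.
# Only rational operations are allowed; any other function is an error.
rf_from_expr <- function(e, allowed = NULL) {
  rec <- function(e) {
    if (is.numeric(e)) {
      q <- .as_rat(as.numeric(e))
      return(rf_const(q[1], q[2]))
    }
    if (is.symbol(e)) {
      v <- as.character(e)
      if (!is.null(allowed) && !(v %in% allowed))
        stop("undeclared symbol: ", v, call. = FALSE)
      return(rf_var(v))
    }
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (op == "(") return(rec(e[[2]]))
      if (op == "+" && length(e) == 2) return(rec(e[[2]]))
      if (op == "-" && length(e) == 2) return(rf_neg(rec(e[[2]])))
      if (op == "+") return(rf_add(rec(e[[2]]), rec(e[[3]])))
      if (op == "-") return(rf_sub(rec(e[[2]]), rec(e[[3]])))
      if (op == "*") return(rf_mul(rec(e[[2]]), rec(e[[3]])))
      if (op == "/") return(rf_div(rec(e[[2]]), rec(e[[3]])))
      if (op == "^") {
        k <- e[[3]]
        if (!is.numeric(k) || k != round(k))
          stop("only integer powers are supported", call. = FALSE)
        return(rf_pow(rec(e[[2]]), k))
      }
      stop("unsupported (non-rational) operation: ", op, call. = FALSE)
    }
    stop("cannot interpret expression component: ", deparse(e), call. = FALSE)
  }
  rec(e)
}

rf_from_string <- function(s, allowed = NULL) {
  rf_from_expr(str2lang(s), allowed)
}

rf_to_expr <- function(a) str2lang(rf_to_string(a))
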