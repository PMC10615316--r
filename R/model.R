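#' Symbolic rational ODE models
#'
#' An `ode_model` represents a system of nonlinear ordinary differential
#' equations \eqn{\dot x = f(x, p)} with measurable output \eqn{y = g(x, p)},
#' where every right-hand side is a ratio of polynomials in the states with
#' parameter coefficients. This is the common ground of reaction-rate models
#' in systems biology: mass-action monomials plus rational saturation terms
#' (Michaelis-Menten/Monod, Hill, saturating feedback).
#'
#' @param name model name.
#' @param states character vector of state variable names (order defines the
#'   state vector).
#' @param params character vector of parameter names. Must be disjoint from
#'   `states`.
#' @param dynamics character vector (or list of expressions) with one
#'   right-hand side per state, in conventional infix notation.
#' @param outputs optional character vector of output expressions; defaults to
#'   all states (a fully observed system).
#' @param x0 optional named numeric vector of initial conditions.
#' @param param_values optional named numeric vector of nominal parameter
#'   values.
#' @param known character vector naming parameters whose values are treated
#'   as known (excluded from identifiability questions).
#' @return an object of class `ode_model`.
#' @export
ode_model <- function(name, states, params, dynamics, outputs = NULL,
                      x0 = NULL, param_values = NULL, known = character()) {
  states <- as.character(states); params <- as.character(params)
  if (length(intersect(states, params)))
    stop("state/parameter namespaces collide: ",
         paste(intersect(states, params), collapse = ", "))
  if (anyDuplicated(c(states, params)))
    stop("duplicated symbol declarations")
  dyn <- lapply(dynamics, function(d) if (is.character(d)) str2lang(d) else d)
  if (length(dyn) != length(states))
    stop("structural error: ", length(dyn), " dynamics entries for ",
         length(states), " states")
  names(dyn) <- states
  if (is.null(outputs)) outputs <- states
  out <- lapply(outputs, function(d) if (is.character(d)) str2lang(d) else d)
  allowed <- c(states, params)
  for (e in c(dyn, out)) {
    bad <- setdiff(all.vars(e), allowed)
    if (length(bad))
      stop("undeclared symbol in expression: ", paste(bad, collapse = ", "))
    rf_from_expr(e, allowed)  # errors on non-rational structure
  }
  bad_known <- setdiff(known, params)
  if (length(bad_known)) stop("unknown names in `known`: ",
                              paste(bad_known, collapse = ", "))
  m <- structure(list(name = name, states = states, params = params,
                      dynamics = dyn, outputs = out,
                      x0 = x0, param_values = param_values,
                      known = known),
                 class = "ode_model")
  m
}

#' Parameters treated as unknown in identifiability analysis
#' @param model an `ode_model`.
#' @return character vector.
#' @export
unknown_params <- function(model) setdiff(model$params, model$known)

#' @export
print.ode_model <- function(x, ...) {
  cat("ode_model:", x$name, "\n")
  cat(" states (", length(x$states), "): ",
      paste(x$states, collapse = ", "), "\n", sep = "")
  cat(" params (", length(x$params), "): ",
      paste(x$params, collapse = ", "), "\n", sep = "")
  for (s in x$states)
    cat("  d", s, "/dt = ", deparse1(x$dynamics[[s]]), "\n", sep = "")
  outs <- vapply(x$outputs, deparse1, character(1))
  if (!identical(outs, x$states))
    cat(" outputs:", paste(outs, collapse = ", "), "\n")
  if (!is.null(x$param_values))
    cat(" values:", paste(names(x$param_values), signif(x$param_values, 6),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# ---- structured-text model definitions ------------------------------------

#' Parse a model definition
#'
#' Reads the flat key/value model format: `name:`, `states:`, `params:` lines,
#' one `d<state>/dt = <expression>` line per state, and optional `outputs:`,
#' `x0:`, `values:` and `known:` lines. Values accept fractions (`8/3`).
#'
#' @param text a character vector of lines, or a single string.
#' @return an `ode_model`.
#' @export
parse_model <- function(text) {
  if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n")[[1]]
  text <- trimws(text)
  text <- text[nzchar(text) & !startsWith(text, "#")]
  fields <- list(); dyn <- list()
  for (ln in text) {
    if (grepl("^d[^=/]+/dt *=", ln)) {
      st <- sub("^d([^=/]+)/dt *=.*$", "\\1", ln)
      ex <- sub("^d[^=/]+/dt *= *", "", ln)
      dyn[[trimws(st)]] <- ex
    } else if (grepl("^[A-Za-z_][A-Za-z0-9_]* *:", ln)) {
      key <- sub(" *:.*$", "", ln)
      val <- sub("^[^:]*: *", "", ln)
      fields[[key]] <- val
    } else stop("unparseable model definition line: ", ln)
  }
  need <- function(k) {
    if (is.null(fields[[k]])) stop("model definition lacks `", k, ":`")
    fields[[k]]
  }
  split_names <- function(s) {
    s <- gsub(",", " ", s)
    strsplit(trimws(s), " +")[[1]]
  }
  parse_assign <- function(s) {
    if (is.null(s)) return(NULL)
    parts <- split_names(s)
    kv <- strsplit(parts, "=")
    vals <- vapply(kv, function(p) {
      if (length(p) != 2) stop("expected name=value, got: ", paste(p, collapse = "="))
      eval(str2lang(p[2]), baseenv())
    }, numeric(1))
    names(vals) <- vapply(kv, `[`, character(1), 1)
    vals
  }
  states <- split_names(need("states"))
  missing_dyn <- setdiff(states, names(dyn))
  if (length(missing_dyn) || length(dyn) != length(states))
    stop("structural error: need exactly one d<state>/dt line per state; ",
         "missing: ", paste(missing_dyn, collapse = ", "))
  ode_model(name = if (is.null(fields$name)) "model" else fields$name,
            states = states,
            params = if (is.null(fields$params)) character()
                     else split_names(fields$params),
            dynamics = dyn[states],
            outputs = if (is.null(fields$outputs)) NULL
                      else split_names(fields$outputs),
            x0 = parse_assign(fields$x0),
            param_values = parse_assign(fields$values),
            known = if (is.null(fields$known)) character()
                    else split_names(fields$known))
}

#' Read a model definition file
#' @param path file path (model definition text or `.json` serialization).
#' @return an `ode_model`.
#' @export
read_model <- function(path) {
  if (grepl("\\.json$", path)) return(model_from_json(path))
  parse_model(readLines(path))
}

#' Serialize a model to text definition format
#' @param model an `ode_model`.
#' @return character vector of lines.
#' @export
format_model <- function(model) {
  lines <- c(paste("name:", model$name),
             paste("states:", paste(model$states, collapse = " ")),
             paste("params:", paste(model$params, collapse = " ")))
  for (s in model$states)
    lines <- c(lines, paste0("d", s, "/dt = ", deparse1(model$dynamics[[s]])))
  outs <- vapply(model$outputs, deparse1, character(1))
  if (!identical(outs, model$states))
    lines <- c(lines, paste("outputs:", paste(outs, collapse = " ")))
  if (!is.null(model$x0))
    lines <- c(lines, paste("x0:", paste(names(model$x0), model$x0,
                                         sep = "=", collapse = " ")))
  if (!is.null(model$param_values))
    lines <- c(lines, paste("values:",
                            paste(names(model$param_values),
                                  vapply(model$param_values, format,
                                         character(1), digits = 17,
                                         trim = TRUE, scientific = FALSE),
                                  sep = "=", collapse = " ")))
  if (length(model$known))
    lines <- c(lines, paste("known:", paste(model$known, collapse = " ")))
  lines
}

#' Write a model definition file
#' @param model an `ode_model`.
#' @param path destination (`.json` for JSON serialization, else text format).
#' @export
write_model <- function(model, path) {
  if (grepl("\\.json$", path)) return(model_to_json(model, path))
  writeLines(format_model(model), path)
  invisible(path)
}

model_to_json <- function(model, path) {
  obj <- list(name = model$name, states = model$states, params = model$params,
              dynamics = vapply(model$dynamics, deparse1, character(1)),
              outputs = vapply(model$outputs, deparse1, character(1)),
              x0 = as.list(model$x0), param_values = as.list(model$param_values),
              known = model$known)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ode_model(name = obj$name, states = obj$states,
            params = if (length(obj$params)) obj$params else character(),
            dynamics = as.list(obj$dynamics),
            outputs = if (length(obj$outputs)) as.list(obj$outputs) else NULL,
            x0 = if (length(obj$x0)) unlist(obj$x0) else NULL,
            param_values = if (length(obj$param_values)) unlist(obj$param_values)
                           else NULL,
            known = if (length(obj$known)) obj$known else character())
}

# ---- rational form ---------------------------------------------------------

#' Rewrite dynamics in implicit rational form
#'
#' Combines each state's right-hand side over a common denominator, giving the
#' implicit representation \eqn{\dot x_i D_i(x) = N_i(x)} with polynomial
#' numerator and denominator. Degrees are reported as total degrees in the
#' state variables (parameters act as coefficients). Denominators are
#' normalized so that the constant term equals 1 when present, otherwise the
#' leading coefficient equals 1.
#'
#' @param model an `ode_model`.
#' @return a list of class `rational_form`: per state, `num`, `den` (exact
#'   polynomials), `deg_num`, `deg_den` and printable strings.
#' @export
to_rational_form <- function(model) {
  allowed <- c(model$states, model$params)
  out <- lapply(model$states, function(s) {
    r <- tryCatch(rf_from_expr(model$dynamics[[s]], allowed),
                  error = function(e)
                    stop("unsupported expression for state ", s, ": ",
                         conditionMessage(e), call. = FALSE))
    list(state = s, num = r$num, den = r$den,
         deg_num = mp_total_deg(r$num, model$states),
         deg_den = mp_total_deg(r$den, model$states),
         num_str = mp_to_string(r$num), den_str = mp_to_string(r$den))
  })
  names(out) <- model$states
  structure(out, class = "rational_form")
}

#' @export
print.rational_form <- function(x, ...) {
  for (f in x)
    cat("d", f$state, "/dt * [", f$den_str, "] = ", f$num_str,
        "   (deg N = ", f$deg_num, ", deg D = ", f$deg_den, ")\n", sep = "")
  invisible(x)
}

#' Maximum numerator/denominator degrees of the implicit form
#' @param model an `ode_model`.
#' @return named integer vector `c(deg_num, deg_den)`: maxima over states of
#'   the total degree (in states) of N and D.
#' @export
rational_degrees <- function(model) {
  rfm <- to_rational_form(model)
  c(deg_num = max(vapply(rfm, function(f) f$deg_num, numeric(1))),
    deg_den = max(vapply(rfm, function(f) f$deg_den, numeric(1))))
}

# ---- augmented system ------------------------------------------------------

#' Augment the state with the unknown parameters
#'
#' Identifiability is analysed by treating unknown parameters as states with
#' zero dynamics: the augmented state is \eqn{\tilde x = (x, p)} with
#' \eqn{\dot p = 0}.
#'
#' @param model an `ode_model`.
#' @return a list with `states` (augmented ordering), `dynamics` (with zeros
#'   appended), `outputs` (unchanged), `n`, `np` and `nxt` (= n + np).
#' @export
augment <- function(model) {
  up <- unknown_params(model)
  dyn <- c(model$dynamics, stats::setNames(rep(list(quote(0)), length(up)), up))
  structure(list(states = c(model$states, up),
                 dynamics = dyn,
                 outputs = model$outputs,
                 known = model$known,
                 known_values = model$param_values[model$known],
                 n = length(model$states), np = length(up),
                 nxt = length(model$states) + length(up)),
            class = "augmented_system")
}
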