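# Channel kinetics: a small arithmetic grammar for voltage-dependent rate
# functions, a parser for the kinetics definition file, and the ChannelSpec
# container.  Rate expressions may use +, -, *, /, exp and parentheses, with
# a single free variable: V (mV) for voltage-dependent gates, t (ms since
# the last spike) for the AHP gate.

#' Compile a rate-function expression
#'
#' Parses an arithmetic expression in one free variable into (i) a
#' vectorised R function and (ii) a flat bytecode vector evaluated by the
#' compiled integrators.  Only `+`, `-`, `*`, `/`, `exp`, parentheses,
#' numeric literals and the declared variable are admitted; anything else is
#' a configuration error.
#'
#' @param text expression as a string, e.g. `"0.32*(V+52)/(1-exp(-(V+52)/4))"`.
#' @param var name of the free variable, `"V"` or `"t"`.
#' @return a list with elements `text`, `fun` (vectorised) and `code`
#'   (numeric bytecode).
#' @examples
#' r <- compile_rate("1.5*exp(-t/60)", var = "t")
#' r$fun(60) # 1.5 * exp(-1)
#' @export
compile_rate <- function(text, var = "V") {
  expr <- tryCatch(parse(text = text)[[1]],
                   error = function(e) stop("cannot parse rate expression: ", text))
  comp <- function(e) {
    if (is.numeric(e)) return(c(0, as.numeric(e)))
    if (is.symbol(e)) {
      if (identical(as.character(e), var)) return(1)
      stop("unknown symbol '", as.character(e), "' in rate expression (expected '",
           var, "'): ", text)
    }
    if (is.call(e)) {
      f <- as.character(e[[1]])
      if (f == "(") return(comp(e[[2]]))
      if (f == "exp") return(c(comp(e[[2]]), 7))
      if (length(e) == 2 && f == "-") return(c(comp(e[[2]]), 6))
      if (length(e) == 2 && f == "+") return(comp(e[[2]]))
      op <- switch(f, "+" = 2, "-" = 3, "*" = 4, "/" = 5,
                   stop("operator '", f, "' not in the rate grammar: ", text))
      return(c(comp(e[[2]]), comp(e[[3]]), op))
    }
    stop("unsupported construct in rate expression: ", text)
  }
  code <- comp(expr)
  env_var <- var
  fun <- function(x) {
    e <- new.env(parent = baseenv())
    assign(env_var, x, envir = e)
    v <- eval(expr, e)
    # removable singularities of linear-over-exponential forms
    bad <- !is.finite(v)
    if (any(bad)) {
      assign(env_var, x[bad] + 1e-8, envir = e)
      v[bad] <- eval(expr, e)
    }
    v + 0 * x
  }
  list(text = text, fun = fun, code = code)
}

#' Construct a channel specification
#'
#' A channel has a maximal conductance `g` (mS/cm^2), a reversal potential
#' `E` (mV) and zero or more gates.  Each gate carries a label, an integer
#' exponent and a pair of opening/closing rate functions (1/ms).  The leak
#' channel has no gates (open fraction identically 1); the AHP gate's
#' opening rate is a function of time since the last spike.
#'
#' @param name channel label (e.g. `"NaT"`, `"h"`, `"AHP"`, `"L"`).
#' @param g maximal conductance, mS/cm^2 (non-negative).
#' @param E reversal potential, mV.
#' @param gates list of gates, each a list with `label`, `exponent`,
#'   `alpha`, `beta` (strings in the rate grammar).
#' @return an object of class `channel_spec`.
#' @export
channel_spec <- function(name, g, E, gates = list()) {
  stopifnot(is.numeric(g), length(g) == 1, g >= 0, is.numeric(E))
  gl <- lapply(gates, function(gt) {
    stopifnot(!is.null(gt$label), gt$exponent >= 1)
    ahp <- identical(name, "AHP")
    a <- compile_rate(gt$alpha, var = if (ahp) "t" else "V")
    b <- compile_rate(gt$beta, var = if (ahp) "t" else "V")
    if (!ahp) {
      vv <- seq(-120, 60, by = 1)
      if (any(a$fun(vv) < -1e-12) || any(b$fun(vv) < -1e-12))
        stop("rate function negative on [-120, 60] mV for gate ", gt$label,
             " of channel ", name)
    }
    list(label = gt$label, exponent = as.integer(gt$exponent),
         alpha = a, beta = b, ahp = ahp)
  })
  structure(list(name = name, g = g, E = E, gates = gl),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel %s>  g = %g mS/cm^2, E = %g mV\n", x$name, x$g, x$E))
  for (gt in x$gates)
    cat(sprintf("  gate %s^%d: alpha = %s ; beta = %s\n", gt$label,
                gt$exponent, gt$alpha$text, gt$beta$text))
  invisible(x)
}

#' Read a kinetics definition file
#'
#' The file is a plain-text, INI-like description of every channel: per
#' `[Channel]` section, `g = ...`, `E = ...`, one `gate <label> <exponent>`
#' line per gating variable followed by `alpha_<label> = <expr>` and
#' `beta_<label> = <expr>` lines.  Lines starting with `#` are comments.
#' The default file shipped with the package
#' (`system.file("extdata", "kinetics_default.ini", package = "stellate")`)
#' is a documented reconstruction of standard stellate-cell channel
#' kinetics; see its header and the package vignette.
#'
#' @param path path to the definition file.
#' @return named list of [channel_spec()] objects.
#' @export
read_kinetics <- function(path = default_kinetics_file()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  channels <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) {
      gates <- lapply(cur$gates, function(gt) {
        if (is.null(gt$alpha) || is.null(gt$beta))
          stop("gate ", gt$label, " of channel ", cur$name,
               " is missing alpha or beta")
        gt
      })
      channels[[cur$name]] <<- channel_spec(cur$name, cur$g, cur$E, gates)
    }
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      flush()
      cur <- list(name = gsub("^\\[|\\]$", "", ln), g = NA_real_,
                  E = NA_real_, gates = list())
    } else if (grepl("^gate\\s", ln)) {
      parts <- strsplit(ln, "\\s+")[[1]]
      if (length(parts) != 3) stop("malformed gate line: ", ln)
      cur$gates[[parts[2]]] <- list(label = parts[2],
                                    exponent = as.integer(parts[3]))
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      if (key == "g") cur$g <- as.numeric(val)
      else if (key == "E") cur$E <- as.numeric(val)
      else if (grepl("^(alpha|beta)_", key)) {
        lab <- sub("^(alpha|beta)_", "", key)
        which <- sub("_.*$", "", key)
        if (is.null(cur$gates[[lab]]))
          stop("rate for undeclared gate '", lab, "' in channel ", cur$name)
        cur$gates[[lab]][[which]] <- val
      } else if (key != "version") stop("unrecognised key '", key, "'")
    } else stop("malformed kinetics line: ", ln)
  }
  flush()
  if (is.null(channels[["L"]]) || length(channels[["L"]]$gates) > 0)
    stop("kinetics file must define a gateless leak channel [L]")
  channels
}

#' Path of the default (reconstructed) kinetics definition file
#' @return file path.
#' @export
default_kinetics_file <- function() {
  system.file("extdata", "kinetics_default.ini", package = "stellate",
              mustWork = TRUE)
}
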