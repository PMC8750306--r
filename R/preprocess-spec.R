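# operator registry: parameter defaults plus stateful fit/apply pairs.
# fit() sees training rows (and optionally the training class indicator);
# apply() must work on any rows using only the fitted state.
pp_registry <- function() {
  list(
    snv = list(
      defaults = list(),
      fit = NULL,
      apply = function(X, state, p) snv(X)
    ),
    detrend = list(
      defaults = list(deg = 2),
      fit = NULL,
      apply = function(X, state, p) detrend_poly(X, p$deg)
    ),
    msc = list(
      defaults = list(mode = "mean"),
      fit = function(X, Y, p) list(reference = colMeans(X)),
      apply = function(X, state, p) {
        msc_apply(X, state$reference, p$mode, p$weights)
      }
    ),
    emsc = list(
      defaults = list(deg = 2),
      fit = function(X, Y, p) list(reference = colMeans(X)),
      apply = function(X, state, p) emsc_apply(X, state$reference, p$deg)
    ),
    savgol = list(
      defaults = list(w = 11, p = 2, d = 0),
      fit = NULL,
      apply = function(X, state, p) savgol(X, p$w, p$p, p$d)
    ),
    gapseg = list(
      defaults = list(gap = 5, seg = 5, order = 2),
      fit = NULL,
      apply = function(X, state, p) gap_segment(X, p$gap, p$seg, p$order)
    ),
    center = list(
      defaults = list(mode = "mean"),
      fit = function(X, Y, p) list(stats = center_fit(X, p$mode)),
      apply = function(X, state, p) center_cols(X, p$mode, state$stats)
    ),
    osc = list(
      defaults = list(ncomp = 1),
      fit = function(X, Y, p) {
        if (is.null(Y)) abort("OSC in a chain requires training labels (Y_train)")
        list(model = osc_fit(X, Y, p$ncomp))
      },
      apply = function(X, state, p) osc_apply(state$model, X)
    ),
    dwt = list(
      defaults = list(family = "daub_short", lo = NA, hi = NA),
      fit = NULL,
      apply = function(X, state, p) {
        levels <- if (is.na(p$lo)) NULL else p$lo:p$hi
        dwt_features(X, p$family, levels)
      }
    ),
    quarter = list(
      defaults = list(q = "full"),
      fit = NULL,
      apply = function(X, state, p) split_quarters(X, p$q)
    )
  )
}

#' Pre-processing chains
#'
#' A `pp_spec` is an ordered, serialisable chain of spectral operators.
#' Chains are written in a compact string grammar used as combination ids in
#' screening reports: steps separated by `|`, parameters in parentheses,
#' e.g. `"snv|detrend(deg=2)"` or `"msc(mode=mean)|savgol(w=11,p=2,d=1)"`.
#' Available operators: `snv`, `detrend(deg)`, `msc(mode)`, `emsc(deg)`,
#' `savgol(w,p,d)`, `gapseg(gap,seg,order)`, `center(mode)`, `osc(ncomp)`,
#' `dwt(family,lo,hi)`, `quarter(q)`.
#'
#' @param x A chain string, a list of steps (each `list(op =, params =)`),
#'   or an existing `pp_spec`.
#' @return A `pp_spec` object; `format()` returns the canonical string.
#' @examples
#' pp_spec("snv|savgol(w=11,p=2,d=1)")
#' @export
pp_spec <- function(x = character()) {
  if (inherits(x, "pp_spec")) return(x)
  reg <- pp_registry()
  steps <- if (is.character(x)) {
    if (length(x) > 1) abort("`x` must be a single chain string")
    if (length(x) == 0 || !nzchar(x)) list() else {
      lapply(strsplit(x, "|", fixed = TRUE)[[1]], parse_step)
    }
  } else if (is.list(x)) x else abort("cannot interpret `x` as a pre-processing chain")
  steps <- lapply(steps, function(st) {
    if (is.character(st)) st <- list(op = st, params = list())
    if (is.null(st$params)) st$params <- list()
    if (!st$op %in% names(reg)) abort(sprintf("unknown operator '%s'", st$op))
    unknown <- setdiff(setdiff(names(st$params), "weights"), names(reg[[st$op]]$defaults))
    if (length(unknown)) {
      abort(sprintf("unknown parameter(s) for %s: %s", st$op, paste(unknown, collapse = ", ")))
    }
    st$params <- modifyList(reg[[st$op]]$defaults, st$params)
    st
  })
  structure(list(steps = steps), class = "pp_spec")
}

parse_step <- function(s) {
  s <- trimws(s)
  m <- stringr::str_match(s, "^([a-z_]+)(?:\\(([^)]*)\\))?$")
  if (is.na(m[1, 1])) abort(sprintf("cannot parse step '%s'", s))
  params <- list()
  if (!is.na(m[1, 3]) && nzchar(m[1, 3])) {
    for (kv in strsplit(m[1, 3], ",", fixed = TRUE)[[1]]) {
      parts <- strsplit(trimws(kv), "=", fixed = TRUE)[[1]]
      if (length(parts) != 2) abort(sprintf("bad parameter '%s' in step '%s'", kv, s))
      val <- trimws(parts[2])
      num <- suppressWarnings(as.numeric(val))
      params[[trimws(parts[1])]] <- if (is.na(num)) val else num
    }
  }
  list(op = m[1, 2], params = params)
}

#' @rdname pp_spec
#' @param ... Unused.
#' @export
format.pp_spec <- function(x, ...) {
  if (!length(x$steps)) return("raw")
  paste(vapply(x$steps, function(st) {
    p <- st$params[setdiff(names(st$params), "weights")]
    if (!length(p)) return(st$op)
    args <- paste(names(p), vapply(p, function(v) as.character(v), character(1)),
                  sep = "=", collapse = ",")
    sprintf("%s(%s)", st$op, args)
  }, character(1)), collapse = "|")
}

#' @export
print.pp_spec <- function(x, ...) {
  cat("<pp_spec> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Fit a pre-processing chain on training rows and apply it everywhere
#'
#' Stateful steps (MSC/EMSC reference, centering statistics, OSC weights)
#' are fitted on `X_train` only; the identical parameterisation is then
#' applied to both partitions, so no test information ever enters fitted
#' state. Channel-trimming steps (gap-segment, quarters) propagate their
#' retained-channel mask; feature-space steps (DWT) clear it.
#'
#' @param spec A [pp_spec()] or chain string.
#' @param X_train Training spectra matrix.
#' @param X_test Optional test spectra matrix (same channels).
#' @param Y_train Optional training labels (factor/character or indicator
#'   matrix); required when the chain contains `osc`.
#' @return A `pp_fit` list: `train` and `test` (transformed matrices),
#'   `channels` (original channel index per retained column, or `NULL` after
#'   a feature-space step), `states`, `spec`.
#' @export
apply_chain <- function(spec, X_train, X_test = NULL, Y_train = NULL) {
  spec <- pp_spec(spec)
  reg <- pp_registry()
  X_train <- as.matrix(X_train)
  if (!is.null(X_test)) {
    X_test <- as.matrix(X_test)
    if (ncol(X_test) != ncol(X_train)) abort("train and test channel counts differ")
  }
  if (!is.null(Y_train) && (is.factor(Y_train) || is.character(Y_train))) {
    Y_train <- class_indicator(Y_train)
  }
  channels <- seq_len(ncol(X_train))
  states <- vector("list", length(spec$steps))
  for (i in seq_along(spec$steps)) {
    st <- spec$steps[[i]]
    entry <- reg[[st$op]]
    state <- if (!is.null(entry$fit)) entry$fit(X_train, Y_train, st$params)
    states[[i]] <- state
    out_train <- entry$apply(X_train, state, st$params)
    kept <- attr(out_train, "channels")
    if (!is.null(X_test)) X_test <- entry$apply(X_test, state, st$params)
    X_train <- out_train
    if (st$op == "dwt") {
      channels <- NULL
    } else if (!is.null(kept)) {
      channels <- channels[kept]
    }
  }
  structure(
    list(train = strip_channels(X_train), test = strip_channels(X_test),
         channels = channels, states = states, spec = spec),
    class = "pp_fit"
  )
}

strip_channels <- function(X) {
  if (is.null(X)) return(NULL)
  attr(X, "channels") <- NULL
  X
}

#' Apply an already-fitted chain to new spectra
#'
#' @param fit A `pp_fit` from [apply_chain()].
#' @param X_new Matrix with the original (pre-chain) channel count.
#' @return Transformed matrix.
#' @export
pp_apply <- function(fit, X_new) {
  stopifnot(inherits(fit, "pp_fit"))
  reg <- pp_registry()
  X <- as.matrix(X_new)
  for (i in seq_along(fit$spec$steps)) {
    st <- fit$spec$steps[[i]]
    X <- reg[[st$op]]$apply(X, fit$states[[i]], st$params)
  }
  strip_channels(X)
}
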