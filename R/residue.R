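#' Residue functions for tracer transport
#'
#' The residue function `R(t)` is the fraction of tracer still inside a
#' vascular territory `t` seconds after arrival; `R(0) = 1` and `R` is
#' non-increasing. Tissue is modeled with a biexponential residue
#' designating fast- and slow-flowing compartments,
#' `R(t) = f*exp(-t*t1) + (1-f)*exp(-t*t2)`, with mean transit time
#' `MTT = f/t1 + (1-f)/t2`. The defaults (`f = 0.92`, `t1 = 0.68`,
#' `t2 = 0.05`) give an MTT of about 3 s. A vein is treated as a single
#' well-mixed compartment with `R(t) = exp(-t/mtt)` (default 4 s).
#'
#' @param f Flow fraction of the fast compartment (0..1).
#' @param t1,t2 Fast and slow rate constants (1/s, > 0).
#' @param mtt Mean transit time of the monoexponential residue (s, > 0).
#' @return An object of class `residue_fn`.
#' @examples
#' residue_mtt(biexponential_residue()) # 2.953
#' residue_value(monoexponential_residue(4), 4) # exp(-1)
#' @name residue
NULL

#' @rdname residue
#' @export
biexponential_residue <- function(f = 0.92, t1 = 0.68, t2 = 0.05) {
  if (f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  if (t1 <= 0 || t2 <= 0) stop("rate constants must be > 0", call. = FALSE)
  structure(list(kind = "biexponential", f = f, t1 = t1, t2 = t2),
            class = "residue_fn")
}

#' @rdname residue
#' @export
monoexponential_residue <- function(mtt = 4) {
  if (mtt <= 0) stop("mtt must be > 0", call. = FALSE)
  structure(list(kind = "monoexponential", mtt = mtt), class = "residue_fn")
}

#' Evaluate a residue function
#'
#' @param residue A `residue_fn`.
#' @param t Times (s, >= 0).
#' @return `R(t)`, in (0, 1].
#' @export
residue_value <- function(residue, t) {
  if (any(t < 0)) stop("residue functions are defined for t >= 0", call. = FALSE)
  switch(residue$kind,
    biexponential = residue$f * exp(-t * residue$t1) +
      (1 - residue$f) * exp(-t * residue$t2),
    monoexponential = exp(-t / residue$mtt)
  )
}

#' Mean transit time of a residue function
#'
#' Closed form: `f/t1 + (1-f)/t2` for the biexponential family, `mtt` for
#' the monoexponential one. Equals the integral of `R(t)` over `[0, Inf)`.
#'
#' @param residue A `residue_fn`.
#' @return Mean transit time (seconds).
#' @export
residue_mtt <- function(residue) {
  switch(residue$kind,
    biexponential = residue$f / residue$t1 + (1 - residue$f) / residue$t2,
    monoexponential = residue$mtt
  )
}

#' @export
print.residue_fn <- function(x, ...) {
  cat("<residue_fn>", x$kind, " MTT:", signif(residue_mtt(x), 4), "s\n")
  invisible(x)
}
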