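#' @title Physical constants of the Ac-225 decay chain
#' @description
#' The Ac-225 series (Ac-225 -> Fr-221 -> At-217 -> Bi-213 -> {Po-213 | Tl-209}
#' -> Pb-209) emits four alpha particles per Ac-225 decay: 5.8 MeV (Ac-225),
#' 6.3 MeV (Fr-221), 7.1 MeV (At-217), and either 8.4 MeV (Po-213, via the
#' 97.8% beta branch of Bi-213) or 5.9 MeV (the 2.2% alpha branch of Bi-213).
#' Constants are loaded from a packaged CSV so that nuclear-data updates need
#' no code change. The canonical internal time unit is hours.
#' @name chain_physics
NULL

# hours per unit of each supported time unit
.TIME_UNIT_HOURS <- c(us = 1 / 3.6e9, ms = 1 / 3.6e6, s = 1 / 3600,
                      min = 1 / 60, h = 1, d = 24)

#' Convert a duration to hours
#'
#' @param value numeric duration value(s).
#' @param unit one of `"us"`, `"ms"`, `"s"`, `"min"`, `"h"`, `"d"`.
#' @return duration in hours.
#' @export
as_hours <- function(value, unit = "h") {
  unit <- match.arg(unit, names(.TIME_UNIT_HOURS))
  value * .TIME_UNIT_HOURS[[unit]]
}

#' Decay constant from half-life
#'
#' Returns `ln(2)/half_life` in inverse hours regardless of the input unit.
#'
#' @param half_life half-life (must be positive).
#' @param unit time unit of `half_life` (default hours).
#' @return decay constant in h^-1.
#' @examples
#' decay_constant(45.6, "min")  # Bi-213, ~0.912 h^-1
#' @export
decay_constant <- function(half_life, unit = "h") {
  if (!is.numeric(half_life) || any(!is.finite(half_life)) || any(half_life <= 0)) {
    abort_acdosim("half-life must be positive and finite", "acdosim_invalid_input")
  }
  log(2) / as_hours(half_life, unit)
}

.parse_pairs <- function(s) {
  # "5.9:0.022;8.4:0.978" -> data.frame(value, fraction)
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(value = numeric(0), fraction = numeric(0)))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(value = vapply(parts, function(p) as.numeric(p[1]), 0),
             fraction = vapply(parts, function(p) as.numeric(p[2]), 0))
}

.parse_parents <- function(s) {
  if (is.na(s) || s == "NA" || !nzchar(s)) return(list())
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  out <- lapply(parts, function(p) as.numeric(p[2]))
  names(out) <- vapply(parts, function(p) p[1], "")
  out
}

.chain_cache <- new.env(parent = emptyenv())

#' The Ac-225 decay chain
#'
#' Loads the packaged nuclide-constants table and returns a validated
#' `decay_chain` object: an ordered list of nuclides from Ac-225 through
#' Pb-209 with half-lives (canonical unit hours), decay constants, per-decay
#' alpha emissions, gamma emission probabilities, photopeak energies and
#' branching fractions.
#'
#' @param constants_csv path to an alternative constants table with the same
#'   columns as the packaged `extdata/ac225_chain.csv`.
#' @return an object of class `decay_chain`.
#' @export
ac225_chain <- function(constants_csv = NULL) {
  if (is.null(constants_csv)) {
    if (!is.null(.chain_cache$default)) return(.chain_cache$default)
    constants_csv <- system.file("extdata", "ac225_chain.csv", package = "acdosim")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.csv(constants_csv, stringsAsFactors = FALSE)
  nucs <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    hl_h <- as_hours(row$half_life_value, row$half_life_unit)
    alpha <- .parse_pairs(as.character(row$alpha_energies))
    names(alpha) <- c("energy_mev", "probability")
    if (any(alpha$probability < 0 | alpha$probability > 1) ||
        row$gamma_probability < 0 || row$gamma_probability > 1) {
      abort_acdosim("emission probabilities must lie in [0, 1]", "acdosim_invalid_input")
    }
    structure(list(
      name = row$name,
      half_life_h = hl_h,
      decay_constant_h = log(2) / hl_h,
      alpha_emissions = alpha,
      gamma_probability = row$gamma_probability,
      photopeak_kev = suppressWarnings(as.numeric(row$photopeak_kev)),
      parents = .parse_parents(as.character(row$parents)),
      reference = row$reference
    ), class = "nuclide")
  })
  names(nucs) <- tab$name
  chain <- structure(list(nuclides = nucs, order = tab$name), class = "decay_chain")
  .validate_chain(chain)
  if (cache) .chain_cache$default <- chain
  chain
}

.validate_chain <- function(chain) {
  # branch fractions out of any member must sum to 1
  out_frac <- stats::setNames(numeric(length(chain$order)), chain$order)
  for (nm in chain$order) {
    for (p in names(chain$nuclides[[nm]]$parents)) {
      out_frac[p] <- out_frac[p] + chain$nuclides[[nm]]$parents[[p]]
    }
  }
  has_child <- out_frac > 0
  if (any(abs(out_frac[has_child] - 1) > 1e-9)) {
    abort_acdosim("branch fractions out of a chain member must sum to 1",
                  "acdosim_invalid_input")
  }
  # parents must precede children (acyclic, ordered by descent)
  pos <- stats::setNames(seq_along(chain$order), chain$order)
  for (nm in chain$order) {
    for (p in names(chain$nuclides[[nm]]$parents)) {
      if (pos[[p]] >= pos[[nm]]) {
        abort_acdosim("decay chain must be ordered parent-before-daughter",
                      "acdosim_invalid_input")
      }
    }
  }
  invisible(chain)
}

#' Look up one nuclide of the chain
#' @param name nuclide name, e.g. `"Bi-213"`.
#' @param chain a `decay_chain`.
#' @return a `nuclide` object.
#' @export
chain_nuclide <- function(name, chain = ac225_chain()) {
  if (!name %in% names(chain$nuclides)) {
    abort_acdosim(sprintf("unknown nuclide '%s'", name), "acdosim_lookup_error")
  }
  chain$nuclides[[name]]
}

#' Canonical segments of the alpha-emitting chain
#'
#' The dosimetric partition follows the imaging surrogates: the "Fr" segment
#' (Ac-225, Fr-221, At-217) is represented by the Fr-221 218-keV photopeak,
#' since Fr-221 (4.8 min) and At-217 (32 ms) are too short-lived to migrate
#' from the Ac-225 decay site; the "Bi" segment (Bi-213 and daughters) is
#' represented by the Bi-213 440-keV photopeak. `"full"` is their union.
#'
#' @param label `"Fr"`, `"Bi"` or `"full"`.
#' @param chain a `decay_chain`.
#' @return a `chain_segment` with fields `label`, `members`, `surrogate`.
#' @export
chain_segment <- function(label = c("Fr", "Bi", "full"), chain = ac225_chain()) {
  label <- match.arg(label)
  members <- switch(label,
    Fr = c("Ac-225", "Fr-221", "At-217"),
    Bi = c("Bi-213", "Po-213", "Tl-209", "Pb-209"),
    full = chain$order)
  surrogate <- switch(label, Fr = "Fr-221", Bi = "Bi-213", full = NA_character_)
  structure(list(label = label, members = members, surrogate = surrogate),
            class = "chain_segment")
}

# Probability that a decay of the segment head reaches each member,
# following branch fractions (head itself has weight 1).
.segment_weights <- function(segment, chain) {
  w <- stats::setNames(numeric(length(chain$order)), chain$order)
  head <- segment$members[[1]]
  w[head] <- 1
  pos <- match(chain$order, chain$order)
  for (nm in chain$order[seq_along(chain$order) > match(head, chain$order)]) {
    ps <- chain$nuclides[[nm]]$parents
    if (length(ps)) w[nm] <- sum(vapply(names(ps), function(p) w[[p]] * ps[[p]], 0))
  }
  w[segment$members]
}

#' Alpha energy emitted per decay of a segment head
#'
#' Branching-weighted sum of alpha-particle energies released by one decay of
#' the first member of the segment, following the chain through all segment
#' members. For the Fr segment this is 5.8 + 6.3 + 7.1 = 19.2 MeV; for the Bi
#' segment 0.978 x 8.4 + 0.022 x 5.9 = 8.345 MeV.
#'
#' @param segment a `chain_segment`.
#' @param chain a `decay_chain`.
#' @return energy in MeV per decay of the segment head.
#' @export
alpha_energy_per_decay <- function(segment, chain = ac225_chain()) {
  if (!inherits(segment, "chain_segment") || length(segment$members) == 0) {
    abort_acdosim("segment must be a nonempty chain_segment", "acdosim_invalid_input")
  }
  missing <- setdiff(segment$members, names(chain$nuclides))
  if (length(missing)) {
    abort_acdosim(sprintf("unknown nuclide '%s'", missing[1]), "acdosim_lookup_error")
  }
  w <- .segment_weights(segment, chain)
  sum(vapply(seq_along(segment$members), function(i) {
    al <- chain$nuclides[[segment$members[i]]]$alpha_emissions
    w[i] * sum(al$energy_mev * al$probability)
  }, 0))
}

#' Bi-213 activity of a decaying Ac-225/Bi-213 mixture
#'
#' Two-member Bateman solution for the total Bi-213 activity of a sample that
#' contained Ac-225 activity `a_ac0` and Bi-213 activity `a_bi0` at time 0:
#' an ingrowth term fed by Ac-225 decay (with the short-lived intermediates
#' Fr-221 and At-217 treated as instantaneous) plus the decay of the Bi-213
#' initially present,
#' \deqn{A_{Bi}(t) = A_{Ac}(0) \frac{\lambda_{Bi}}{\lambda_{Bi}-\lambda_{Ac}}
#'   (e^{-\lambda_{Ac} t} - e^{-\lambda_{Bi} t}) + A_{Bi}(0) e^{-\lambda_{Bi} t}.}
#'
#' @param t hours since time 0 (vectorized, non-negative).
#' @param a_ac0,a_bi0 Ac-225 and Bi-213 activities at time 0 (Bq, >= 0).
#' @param chain a `decay_chain`.
#' @return Bi-213 activity at `t`, same unit as the inputs.
#' @export
bateman_bi_activity <- function(t, a_ac0, a_bi0, chain = ac225_chain()) {
  if (any(!is.finite(t)) || any(t < 0) || a_ac0 < 0 || a_bi0 < 0) {
    abort_acdosim("times and activities must be non-negative", "acdosim_invalid_input")
  }
  l_ac <- chain$nuclides[["Ac-225"]]$decay_constant_h
  l_bi <- chain$nuclides[["Bi-213"]]$decay_constant_h
  a_ac0 * (l_bi / (l_bi - l_ac)) * (exp(-l_ac * t) - exp(-l_bi * t)) +
    a_bi0 * exp(-l_bi * t)
}

#' Bin-averaged Bi-213 activity
#'
#' Mean of [bateman_bi_activity()] over counting bins `[t_mid - dt/2,
#' t_mid + dt/2]`, computed from the closed-form antiderivative. This is the
#' forward model matching gamma-counter bins, whose expected counts are
#' proportional to the number of decays within the bin.
#'
#' @param t_mid bin midpoints, hours.
#' @param dt_h bin width, hours.
#' @inheritParams bateman_bi_activity
#' @return mean activity over each bin.
#' @export
bateman_bi_bin_average <- function(t_mid, dt_h, a_ac0, a_bi0, chain = ac225_chain()) {
  if (dt_h <= 0) abort_acdosim("bin width must be positive", "acdosim_invalid_input")
  l_ac <- chain$nuclides[["Ac-225"]]$decay_constant_h
  l_bi <- chain$nuclides[["Bi-213"]]$decay_constant_h
  t1 <- t_mid - dt_h / 2
  t2 <- t_mid + dt_h / 2
  if (any(t1 < -1e-12)) abort_acdosim("bins must start at t >= 0", "acdosim_invalid_input")
  int_exp <- function(l, t1, t2) (exp(-l * t1) - exp(-l * t2)) / l
  (a_ac0 * (l_bi / (l_bi - l_ac)) * (int_exp(l_ac, t1, t2) - int_exp(l_bi, t1, t2)) +
     a_bi0 * int_exp(l_bi, t1, t2)) / dt_h
}

#' Secular-equilibrium activity ratio Bi-213 / Ac-225
#'
#' The transient-free limit of the Bateman solution: once the ingrowth
#' transient has decayed, A_Bi/A_Ac equals lambda_Bi / (lambda_Bi - lambda_Ac)
#' (about 1.0032 for this chain).
#'
#' @param chain a `decay_chain`.
#' @return dimensionless ratio.
#' @export
equilibrium_ratio <- function(chain = ac225_chain()) {
  l_ac <- chain$nuclides[["Ac-225"]]$decay_constant_h
  l_bi <- chain$nuclides[["Bi-213"]]$decay_constant_h
  if (l_bi <= l_ac) {
    abort_acdosim("daughter decay constant must exceed the parent's",
                  "acdosim_degenerate_chain")
  }
  l_bi / (l_bi - l_ac)
}

#' Time for the Bateman transient to decay to a given fraction
#'
#' Smallest `t` with `exp(-lambda_Bi * t) <= fraction_remaining`, i.e. the
#' time after which the transient term of the Bateman solution has decayed to
#' the stated fraction and the sample is, to that tolerance, in secular
#' equilibrium. A residual fraction of 0.003 gives about 6.4 h.
#'
#' @param fraction_remaining residual transient fraction, in (0, 1).
#' @param chain a `decay_chain`.
#' @return time in hours.
#' @export
time_to_equilibrium <- function(fraction_remaining, chain = ac225_chain()) {
  if (!is.numeric(fraction_remaining) || length(fraction_remaining) != 1L ||
      !is.finite(fraction_remaining) ||
      fraction_remaining <= 0 || fraction_remaining >= 1) {
    abort_acdosim("fraction_remaining must lie strictly in (0, 1)",
                  "acdosim_invalid_input")
  }
  l_bi <- chain$nuclides[["Bi-213"]]$decay_constant_h
  log(1 / fraction_remaining) / l_bi
}
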