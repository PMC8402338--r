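# Mathematical core of the model: asymmetric filtering, the opinion update,
# initial-opinion sampling, patient classification and the doctor-commitment
# refresh.  These functions are vectorised where natural and are also the
# building blocks of the pure-R reference engine; the compiled engine
# re-implements them with the identical RNG draw order.

# uniform integer on 1..n from R's RNG stream; guard against the (purely
# floating-point) possibility of unif_rand()*n rounding up to n
rint <- function(n) {
  j <- 1L + as.integer(floor(stats::runif(1) * n))
  if (j > n) n else j
}

#' Asymmetric information-filtering factor
#'
#' Multiplicative discount f in \[0, 1\] applied to a source's influence,
#' encoding biased assimilation with an emotional asymmetry:
#' \itemize{
#'   \item Undecided non-activists (|Oi| <= FT) do not filter: f = 1.
#'   \item Committed non-activists (|Oi| > FT) accept same-sign sources
#'     fully (f = 1) and discount opposing ones by
#'     f = (B - |Oi|) / (B - FT), with B the opinion-bound magnitude.
#'   \item Messages are exempt from non-activist filtering (f = 1 regardless
#'     of sign), modelling the emotional/narrative appeal of infosphere
#'     content.
#'   \item Activists (Oi < AT) discount even same-sign sources by
#'     (B - |Oi|) / (B - FT) and totally reject opposing ones (f = 0) —
#'     message or not.
#' }
#' Opinion 0 is treated as agreeing with either sign.  The same-sign
#' activist branch is clamped to 1 (reachable only when AT > -FT, i.e.
#' outside the default regime).
#'
#' @param o_i Opinion(s) of the receiving patient.
#' @param o_s Opinion(s) of the information source.
#' @param is_activist Logical: is the receiver currently an activist?
#' @param source_is_message Logical: is the source an infosphere message?
#' @param params An [model_params()] record (supplies FT and the bound
#'   magnitude B).
#' @return Numeric factor(s) in \[0, 1\]; recycled over the longest input.
#' @examples
#' p <- model_params()
#' filtering_factor(-1.5, 1, FALSE, FALSE, p)  # 0.5: committed, opposing
#' filtering_factor(-1.5, 1, FALSE, TRUE, p)   # 1: message exemption
#' filtering_factor(-1.9, 1.5, TRUE, TRUE, p)  # 0: activist total rejection
#' @export
filtering_factor <- function(o_i, o_s, is_activist, source_is_message,
                             params) {
  b <- params$opinion_bounds[2]
  ft <- params$filtering_threshold
  n <- max(length(o_i), length(o_s), length(is_activist),
           length(source_is_message))
  o_i <- rep_len(o_i, n)
  o_s <- rep_len(o_s, n)
  is_activist <- rep_len(as.logical(is_activist), n)
  source_is_message <- rep_len(as.logical(source_is_message), n)
  if (any(abs(o_i) > b) || any(abs(o_s) > b)) {
    stop("opinions outside opinion_bounds")
  }
  same_sign <- (o_i >= 0 & o_s >= 0) | (o_i <= 0 & o_s <= 0)
  discount <- pmin(1, (b - abs(o_i)) / (b - ft))
  f <- numeric(n)
  act <- is_activist
  f[act] <- ifelse(same_sign[act], discount[act], 0)
  non <- !act
  f[non] <- ifelse(source_is_message[non] | abs(o_i[non]) <= ft |
                     same_sign[non], 1, discount[non])
  f
}

#' Biased-assimilation opinion update
#'
#' Convex combination `o_i * (1 - alpha * f) + o_s * alpha * f`: the patient
#' moves toward the source at a rate set by the acceptance rate `alpha`
#' discounted by the filtering factor `f`.  The result always lies between
#' `o_i` and `o_s`, hence within the opinion bounds whenever both inputs
#' are; no clipping is ever applied.
#'
#' @param o_i Current opinion of the patient.
#' @param o_s Opinion of the source.
#' @param alpha Acceptance rate in (0, 1].
#' @param f Filtering factor in \[0, 1\] (see [filtering_factor()]).
#' @return Updated opinion(s).
#' @examples
#' update_opinion(0, 2, 0.66, 1)  # 1.32
#' @export
update_opinion <- function(o_i, o_s, alpha, f) {
  af <- alpha * f
  if (any(af < 0 | af > 1)) stop("alpha * f must lie in [0, 1]")
  o_i * (1 - af) + o_s * af
}

# one truncated-normal draw by rejection, consuming the R RNG stream in the
# same pattern as the compiled engine; opinion_sd = 0 degenerates to the
# center without touching the stream (as does rnorm with sd = 0)
draw_one_initial_opinion <- function(params) {
  lo <- params$opinion_bounds[1]
  hi <- params$opinion_bounds[2]
  repeat {
    x <- stats::rnorm(1, params$opinion_center, params$opinion_sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Draw initial patient opinions
#'
#' Samples from a normal distribution with mean `opinion_center` and
#' standard deviation `opinion_sd`, truncated to `opinion_bounds`, by
#' rejection.  Used both for the initial population and for the fresh
#' agents replacing patients that age out.
#'
#' @param n Number of draws.
#' @param params An [model_params()] record.
#' @return Numeric vector of `n` opinions within the bounds.
#' @examples
#' set.seed(1)
#' summary(draw_initial_opinion(1000, model_params()))
#' @export
draw_initial_opinion <- function(n, params) {
  vapply(seq_len(n), function(i) draw_one_initial_opinion(params), numeric(1))
}

#' Classify a patient by its opinion
#'
#' Strict-threshold classification: opinion < AT is an `"activist"`
#' (activists also count as antivaxxers in the NAV statistic), AT <=
#' opinion < VT an `"antivaxxer"`, and opinion >= VT a `"vaccinator"`.
#'
#' @param opinion Numeric opinion(s).
#' @param params An [model_params()] record.
#' @return Character vector in `c("vaccinator", "antivaxxer", "activist")`.
#' @examples
#' classify_patient(c(-1.85, -1.2, -1, 0.4), model_params())
#' @export
classify_patient <- function(opinion, params) {
  out <- rep("vaccinator", length(opinion))
  out[opinion < params$vaccination_threshold] <- "antivaxxer"
  out[opinion < params$activism_threshold] <- "activist"
  out
}

# partial Fisher-Yates selection of m indices out of n, consuming one
# uniform per selected index; mirrored verbatim by the compiled engine
sample_indices <- function(n, m) {
  idx <- seq_len(n)
  if (m > 0L) {
    for (j in seq_len(m)) {
      r <- j - 1L + rint(n - j + 1L)
      tmp <- idx[j]; idx[j] <- idx[r]; idx[r] <- tmp
    }
  }
  idx[seq_len(m)]
}

# round-half-up (the base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' Refresh doctor commitment against the current antivaxxer count
#'
#' The number of uncommitted doctors is `round(ND * k * NAV / NP)`
#' (half-up).  Which doctors are uncommitted is a fresh uniform random
#' subset at every refresh; a doctor whose commitment status changed draws
#' a new opinion uniformly from the corresponding range (committed:
#' `committed_doctor_opinion_range`; uncommitted:
#' `uncommitted_doctor_opinion_range`), while unchanged doctors keep
#' theirs.
#'
#' @param doctors A list with numeric `opinion` and logical `uncommitted`,
#'   both of length ND (as produced by this function or the engine
#'   initialiser).
#' @param n_antivax Current number of antivaxxers NAV.
#' @param params An [model_params()] record.
#' @return The updated `doctors` list.
#' @export
refresh_doctor_commitment <- function(doctors, n_antivax, params) {
  nd <- params$n_doctors
  ndu <- as.integer(round_half_up(
    nd * params$doctor_hesitancy_factor * n_antivax / params$n_patients))
  ndu <- min(ndu, nd)
  new_unc <- rep(FALSE, nd)
  new_unc[sample_indices(nd, ndu)] <- TRUE
  cr <- params$committed_doctor_opinion_range
  ur <- params$uncommitted_doctor_opinion_range
  for (d in seq_len(nd)) {
    if (new_unc[d] != doctors$uncommitted[d]) {
      doctors$opinion[d] <- if (new_unc[d]) {
        stats::runif(1, ur[1], ur[2])
      } else {
        stats::runif(1, cr[1], cr[2])
      }
    }
  }
  doctors$uncommitted <- new_unc
  doctors
}
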