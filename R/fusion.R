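# Decision fusion over the binary frame {Healthy, PD}: majority vote,
# Bayesian combination, and Dempster-Shafer evidence combination.

#' Construct a mass function on the frame \{Healthy, PD\}
#'
#' Basic belief assignment with focal sets \{Healthy\}, \{PD\} and the whole
#' frame Theta; masses are non-negative and sum to one.
#'
#' @param healthy,pd,theta Masses of the three focal sets; `theta` defaults
#'   to the complement `1 - healthy - pd`, so `mass_function()` is the
#'   vacuous mass.
#' @return Named numeric vector of class `mass_function`.
#' @export
mass_function <- function(healthy = 0, pd = 0, theta = 1 - healthy - pd) {
  m <- c(Healthy = healthy, PD = pd, Theta = theta)
  if (any(m < -1e-12)) stop("masses must be non-negative")
  if (abs(sum(m) - 1) > 1e-12) stop("masses must sum to 1")
  structure(pmax(m, 0), class = "mass_function")
}

conflict_error <- function(call = sys.call(-1)) {
  structure(class = c("copemd_conflict", "error", "condition"),
            list(message = "total conflict (K = 1): combination undefined",
                 call = call))
}

#' Majority vote over classifier decisions
#'
#' Most frequent label wins. Ties (frequent with four voters) are broken by
#' the class with the highest mean per-class score across classifiers when
#' scores are supplied; without scores a tie falls back to `Healthy`, the
#' conservative call, with a warning.
#'
#' @param decisions Character vector of labels (`Healthy`/`PD`).
#' @param scores Optional named numeric vector `c(Healthy=, PD=)` of mean
#'   per-class scores used only to break ties.
#' @return A single label.
#' @export
majority_vote <- function(decisions, scores = NULL) {
  stopifnot(length(decisions) >= 1L)
  tab <- table(factor(decisions, levels = CLASS_LEVELS))
  if (tab[["PD"]] != tab[["Healthy"]]) {
    return(names(which.max(tab)))
  }
  if (!is.null(scores)) {
    return(names(which.max(scores[CLASS_LEVELS])))
  }
  warning("majority tie with no scores supplied; returning 'Healthy'")
  "Healthy"
}

#' Reliability of a classifier per predicted class
#'
#' Laplace-smoothed conditional correctness estimated from (training-fold)
#' predictions: for each predicted class `d`,
#' `(n(pred = d, truth = d) + 1) / (n(pred = d) + 2)`. Smoothing keeps every
#' estimate strictly inside (0, 1).
#'
#' @param truth,pred Label vectors.
#' @return Named list with elements `Healthy` and `PD`.
#' @export
estimate_reliability <- function(truth, pred) {
  truth <- factor(truth, levels = CLASS_LEVELS)
  pred <- factor(pred, levels = CLASS_LEVELS)
  out <- lapply(CLASS_LEVELS, function(d) {
    (sum(pred == d & truth == d) + 1) / (sum(pred == d) + 2)
  })
  stats::setNames(out, CLASS_LEVELS)
}

#' Class-conditional decision likelihoods of a classifier
#'
#' Laplace-smoothed `P(classifier says d | truth = w)` from (training-fold)
#' predictions: `(n(truth = w, pred = d) + 1) / (n(truth = w) + 2)`.
#'
#' @param truth,pred Label vectors.
#' @return 2x2 matrix, rows = truth, columns = decision.
#' @export
estimate_likelihood <- function(truth, pred) {
  truth <- factor(truth, levels = CLASS_LEVELS)
  pred <- factor(pred, levels = CLASS_LEVELS)
  m <- matrix(NA_real_, 2, 2, dimnames = list(truth = CLASS_LEVELS,
                                              decision = CLASS_LEVELS))
  for (w in CLASS_LEVELS) {
    for (d in CLASS_LEVELS) {
      m[w, d] <- (sum(truth == w & pred == d) + 1) / (sum(truth == w) + 2)
    }
  }
  m
}

#' Simple support mass from one classifier decision
#'
#' Encodes how much the decision should be believed: the decided singleton
#' receives the classifier's reliability for that predicted class, the
#' remainder goes to the whole frame (ignorance), and the opposing singleton
#' receives nothing.
#'
#' @param decision `"Healthy"` or `"PD"`.
#' @param reliability Reliability in (0, 1] of the classifier when it
#'   predicts this class (see [estimate_reliability()]).
#' @return A `mass_function`.
#' @export
build_mass <- function(decision, reliability) {
  if (is.null(reliability) || is.na(reliability)) {
    stop("missing reliability estimate for the deciding classifier")
  }
  stopifnot(decision %in% CLASS_LEVELS, reliability >= 0, reliability <= 1)
  if (decision == "Healthy") {
    mass_function(healthy = reliability, theta = 1 - reliability)
  } else {
    mass_function(pd = reliability, theta = 1 - reliability)
  }
}

#' Dempster's rule of combination
#'
#' Conjunctive combination of two mass functions on \{Healthy, PD\}: products
#' over focal-set intersections, with the conflict mass `K` (products with
#' empty intersection) removed by `1/(1-K)` normalisation. Commutative and
#' associative to numerical precision.
#'
#' @param m1,m2 `mass_function` objects.
#' @return The combined `mass_function`.
#' @export
dempster_combine <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  K <- m1[["Healthy"]] * m2[["PD"]] + m1[["PD"]] * m2[["Healthy"]]
  if (1 - K <= 1e-12) stop(conflict_error())
  h <- m1[["Healthy"]] * m2[["Healthy"]] + m1[["Healthy"]] * m2[["Theta"]] +
    m1[["Theta"]] * m2[["Healthy"]]
  p <- m1[["PD"]] * m2[["PD"]] + m1[["PD"]] * m2[["Theta"]] +
    m1[["Theta"]] * m2[["PD"]]
  th <- m1[["Theta"]] * m2[["Theta"]]
  mass_function(h / (1 - K), p / (1 - K), th / (1 - K))
}

#' Pignistic probabilities of a mass function
#'
#' Splits the mass on the whole frame equally between the two singletons:
#' `BetP(class) = m({class}) + m(Theta)/2`.
#'
#' @param m A `mass_function`.
#' @return Named numeric vector over Healthy and PD.
#' @export
pignistic <- function(m) {
  stopifnot(inherits(m, "mass_function"))
  c(Healthy = m[["Healthy"]] + m[["Theta"]] / 2,
    PD = m[["PD"]] + m[["Theta"]] / 2)
}

#' Dempster-Shafer decision from a set of masses
#'
#' Folds all masses with [dempster_combine()] and decides by maximum
#' pignistic probability; an exact tie goes to `Healthy` (the conservative
#' call). Under total conflict the combination is undefined; when fallback
#' decisions are supplied the function falls back to [majority_vote()] with a
#' warning, otherwise the conflict error propagates.
#'
#' @param masses List of at least two `mass_function` objects.
#' @param fallback_decisions,fallback_scores Passed to [majority_vote()] on
#'   total conflict; `NULL` disables the fallback.
#' @return A single label.
#' @export
ds_decide <- function(masses, fallback_decisions = NULL,
                      fallback_scores = NULL) {
  stopifnot(length(masses) >= 2L)
  combined <- tryCatch(
    Reduce(dempster_combine, masses),
    copemd_conflict = function(e) {
      if (is.null(fallback_decisions)) stop(e)
      warning("total conflict in Dempster combination; falling back to majority vote")
      NULL
    })
  if (is.null(combined)) {
    return(majority_vote(fallback_decisions, fallback_scores))
  }
  bp <- pignistic(combined)
  if (bp[["PD"]] > bp[["Healthy"]]) "PD" else "Healthy"
}

#' Bayesian decision fusion
#'
#' Naive-Bayes combination of classifier decisions:
#' `posterior(w) proportional to prior(w) * prod_c P(decision_c | w)`, with
#' the likelihoods the Laplace-smoothed class-conditional decision
#' probabilities of each classifier (see [estimate_likelihood()]). Smoothing
#' guarantees non-zero likelihoods. Returns the maximum-posterior label; an
#' exact tie goes to `Healthy`.
#'
#' @param decisions Named or ordered character vector of labels, one per
#'   classifier.
#' @param likelihoods List of 2x2 likelihood matrices (rows truth, columns
#'   decision), one per classifier, in the same order as `decisions`.
#' @param priors Class prior probabilities, named `Healthy` and `PD`.
#' @return A single label.
#' @export
bayes_fuse <- function(decisions, likelihoods, priors) {
  stopifnot(length(decisions) == length(likelihoods))
  priors <- priors[CLASS_LEVELS]
  logpost <- log(as.numeric(priors))
  names(logpost) <- CLASS_LEVELS
  for (j in seq_along(decisions)) {
    lk <- likelihoods[[j]]
    logpost <- logpost + log(lk[CLASS_LEVELS, decisions[[j]]])
  }
  if (logpost[["PD"]] > logpost[["Healthy"]]) "PD" else "Healthy"
}
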