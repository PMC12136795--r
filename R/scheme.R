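#' Build a kinetic binding scheme
#'
#' Constructs a \linkS4class{KineticScheme} from a state list and an edge
#' table. Edges marked \code{conc = TRUE} carry second-order rate constants
#' (M^-1 s^-1) that are multiplied by the ligand concentration when the
#' generator matrix is assembled; all other edges are first-order (s^-1).
#'
#' @param states character vector of state names.
#' @param edges data.frame with columns \code{from}, \code{to}, \code{rate}
#'   and optionally \code{conc} (logical, default FALSE).
#' @param observable named character vector mapping each state to
#'   \code{"dark"}, \code{"bound"} or \code{"bound2"}.
#' @param initialState name of the state occupied at time zero (default:
#'   first state).
#' @return a validated \linkS4class{KineticScheme}.
#' @examples
#' twoStateScheme(kon = 1.94e7, koff = 0.045)
#' @export
buildScheme <- function(states, edges, observable, initialState = states[1L]) {
  stopifnot(is.character(states), length(states) >= 1L,
            !anyDuplicated(states))
  if (!all(c("from", "to", "rate") %in% names(edges))) {
    stop("edges must have columns from, to, rate")
  }
  if (is.null(edges$conc)) edges$conc <- FALSE
  if (!all(edges$from %in% states) || !all(edges$to %in% states)) {
    stop("edges reference undeclared states")
  }
  if (any(edges$rate < 0)) stop("negative rate constants are not allowed")
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  n <- length(states)
  R <- matrix(0, n, n, dimnames = list(states, states))
  Cm <- matrix(FALSE, n, n, dimnames = list(states, states))
  for (r in seq_len(nrow(edges))) {
    R[edges$from[r], edges$to[r]] <- edges$rate[r]
    Cm[edges$from[r], edges$to[r]] <- isTRUE(edges$conc[r])
  }
  obs <- observable[states]
  if (anyNA(obs)) stop("observable must name every state")
  new("KineticScheme", stateNames = states, rates = R, concEdges = Cm,
      observableClass = unname(obs),
      initialState = match(initialState, states))
}

#' Generator matrix at a given concentration
#'
#' Assembles the infinitesimal generator Q (rows summing to zero) with
#' concentration-dependent edges scaled by the ligand concentration.
#'
#' @param scheme a \linkS4class{KineticScheme}.
#' @param concentration ligand concentration in nM.
#' @return square numeric matrix Q in s^-1.
#' @export
rateMatrix <- function(scheme, concentration = NA_real_) {
  stopifnot(is(scheme, "KineticScheme"))
  if (any(scheme@concEdges) && (is.na(concentration) || concentration < 0)) {
    stop("scheme has concentration-dependent edges; supply concentration (nM)")
  }
  Q <- scheme@rates
  if (any(scheme@concEdges)) {
    Q[scheme@concEdges] <- Q[scheme@concEdges] * concentration * 1e-9
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of a scheme
#'
#' Solves pi Q = 0, sum(pi) = 1 for the continuous-time chain at the given
#' concentration.
#'
#' @inheritParams rateMatrix
#' @return named numeric vector of stationary state probabilities.
#' @export
stationaryDistribution <- function(scheme, concentration = NA_real_) {
  Q <- rateMatrix(scheme, concentration)
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  setNames(pi / sum(pi), scheme@stateNames)
}

#' Two-state binding scheme U <-> UL
#'
#' @param kon association rate constant, M^-1 s^-1.
#' @param koff dissociation rate constant, s^-1.
#' @return a \linkS4class{KineticScheme} with 2 free parameters.
#' @export
twoStateScheme <- function(kon = 1.94e7, koff = 0.045) {
  buildScheme(
    states = c("U", "UL"),
    edges = data.frame(from = c("U", "UL"), to = c("UL", "U"),
                       rate = c(kon, koff), conc = c(TRUE, FALSE)),
    observable = c(U = "dark", UL = "bound")
  )
}

#' Three-state schemes with one rare off-pathway state
#'
#' \code{threeStateDarkScheme} adds a rare dark state U* from which binding
#' cannot occur; \code{threeStateBoundScheme} adds a rare bound state UL*
#' from which dissociation cannot occur.
#'
#' @inheritParams twoStateScheme
#' @param kUtoUstar,kUstarToU rare dark-state entry/exit rates, s^-1.
#' @param kULtoULstar,kULstarToUL rare bound-state entry/exit rates, s^-1.
#' @return a \linkS4class{KineticScheme} with 4 free parameters.
#' @export
threeStateDarkScheme <- function(kon = 1.94e7, koff = 0.045,
                                 kUtoUstar = 0.002, kUstarToU = 0.002) {
  buildScheme(
    states = c("Ustar", "U", "UL"),
    edges = data.frame(
      from = c("U", "Ustar", "U", "UL"),
      to = c("Ustar", "U", "UL", "U"),
      rate = c(kUtoUstar, kUstarToU, kon, koff),
      conc = c(FALSE, FALSE, TRUE, FALSE)),
    observable = c(Ustar = "dark", U = "dark", UL = "bound"),
    initialState = "U"
  )
}

#' @rdname threeStateDarkScheme
#' @export
threeStateBoundScheme <- function(kon = 1.94e7, koff = 0.045,
                                  kULtoULstar = 0.002, kULstarToUL = 0.002) {
  buildScheme(
    states = c("U", "UL", "ULstar"),
    edges = data.frame(
      from = c("U", "UL", "UL", "ULstar"),
      to = c("UL", "U", "ULstar", "UL"),
      rate = c(kon, koff, kULtoULstar, kULstarToUL),
      conc = c(TRUE, FALSE, FALSE, FALSE)),
    observable = c(U = "dark", UL = "bound", ULstar = "bound"),
    initialState = "U"
  )
}

#' Four-state linear binding scheme U* <-> U <-> UL <-> UL*
#'
#' The default ground-truth scheme: binding occurs in a single step
#' (U -> UL, second order) and both the free RNA and the complex can rarely
#' visit states from which the complex cannot form (U*) or cannot dissociate
#' (UL*). Six free rate parameters. The rare-state rates default to
#' 0.002 s^-1 in each direction; they are assumptions, not measured values,
#' and can be overridden.
#'
#' @inheritParams twoStateScheme
#' @param kUtoUstar,kUstarToU rare dark-state rates, s^-1.
#' @param kULtoULstar,kULstarToUL rare bound-state rates, s^-1.
#' @return a \linkS4class{KineticScheme} with 6 free parameters.
#' @export
fourStateScheme <- function(kon = 1.94e7, koff = 0.045,
                            kUtoUstar = 0.002, kUstarToU = 0.002,
                            kULtoULstar = 0.002, kULstarToUL = 0.002) {
  buildScheme(
    states = c("Ustar", "U", "UL", "ULstar"),
    edges = data.frame(
      from = c("U", "Ustar", "U", "UL", "UL", "ULstar"),
      to = c("Ustar", "U", "UL", "U", "ULstar", "UL"),
      rate = c(kUtoUstar, kUstarToU, kon, koff, kULtoULstar, kULstarToUL),
      conc = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)),
    observable = c(Ustar = "dark", U = "dark", UL = "bound", ULstar = "bound"),
    initialState = "U"
  )
}
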