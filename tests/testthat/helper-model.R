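# Shared fixtures and an independent oracle for the model equations.

canonical_network <- ageing_network()
canonical_params <- grn_params()

# Literal hand transcription of the 13 model ODEs, written term by term
# and independently of the package's edge-grouped evaluation. Used to
# pin the compiled network to the equations.
literal_rhs <- function(x, a = 1, b = 0.05, S = 0.5, n = 4, k = 1,
                        Stress = 0.3, GS = 0.2) {
  A <- function(v) v^n / (S^n + v^n)
  I <- function(v) S^n / (S^n + v^n)
  p53 <- x[1]; Mdm2 <- x[2]; Wip1 <- x[3]; ATM <- x[4]; p21 <- x[5]
  PTEN <- x[6]; AKT <- x[7]; Myc <- x[8]; E2F <- x[9]; RB <- x[10]
  CycE <- x[11]; CycD <- x[12]; ARF <- x[13]
  c(
    a*A(ARF) + a*A(p53) + a*A(ATM) + b*I(Mdm2) + b*I(Wip1) - k*p53,
    a*A(p53) + a*A(AKT) + a*A(Wip1) + b*I(ATM) + b*I(ARF) - k*Mdm2,
    a*A(p53) - k*Wip1,
    a*A(ATM) + a*A(Stress) + b*I(Wip1) - k*ATM,
    a*A(p53) + b*I(AKT) - k*p21,
    a*A(p53) - k*PTEN,
    b*I(PTEN) - k*AKT,
    a*A(GS) - k*Myc,
    b*I(p21) + a*A(E2F) + a*A(Myc) + b*I(RB) - k*E2F,
    a*A(p21) + b*I(CycD) + b*I(CycE) - k*RB,
    a*A(E2F) + b*I(p21) - k*CycE,
    a*A(Myc) + a*A(GS) + b*I(p21) - k*CycD,
    a*A(Myc) - k*ARF
  )
}

# Deterministic reference fixed points (converge + polish from targeted
# starts). The intermediate start keeps ATM low while pushing p53 over
# its activation threshold; the quiescent-high start zeroes the
# cell-cycle arm so the continuation follows the E2F-off branch.
fixed_point_from <- function(x0, network = canonical_network,
                             params = canonical_params) {
  cv <- converge_to_steady_state(network, params, x0)
  refine_fixed_point(cv$state, network, params)$state
}

low_start <- function() rep(0, 13)

intermediate_start <- function() {
  x0 <- stats::setNames(rep(0.1, 13), canonical_network$nodes)
  x0[c("p53", "Wip1", "p21", "PTEN")] <- 1
  x0
}

quiescent_high_start <- function() {
  x0 <- stats::setNames(rep(2, 13), canonical_network$nodes)
  x0[c("Myc", "E2F", "RB", "CycE", "CycD")] <- 0
  x0
}

perturbed_network <- function() {
  delete_edges(canonical_network,
               c("ATM:p53:activation", "ARF:p53:activation"))
}
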