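#' Signed regulatory networks
#'
#' A `grn_network` holds the topology of a gene regulatory network: an
#' ordered set of species (nodes), a signed directed edge list, and a set
#' of constant external inputs (signals that regulate nodes but are never
#' themselves integrated). Together with a [grn_params()] object it fully
#' determines the Hill-kinetics ODE system evaluated by [grn_rhs()].
#'
#' @param nodes character vector of species names (the integration order).
#' @param edges data frame with columns `source`, `target`, `sign`
#'   (`"activation"` or `"inhibition"`). Sources may be nodes or inputs;
#'   targets must be nodes.
#' @param inputs character vector naming the constant inputs (their
#'   levels live in the parameter set, see [grn_params()]).
#' @return An object of class `grn_network`.
#' @seealso [ageing_network()] for the built-in 13-node model,
#'   [delete_edges()] for in-silico perturbations.
#' @export
grn_network <- function(nodes, edges, inputs = character()) {
  nodes <- as.character(nodes)
  inputs <- as.character(inputs)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "sign") %in% names(edges)))
    stop("edges must have columns source, target, sign", call. = FALSE)
  edges <- edges[, c("source", "target", "sign")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.character(edges$sign)

  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  if (length(intersect(nodes, inputs)))
    stop("a name cannot be both node and input", call. = FALSE)
  if (!all(edges$sign %in% c("activation", "inhibition")))
    stop("edge sign must be 'activation' or 'inhibition'", call. = FALSE)
  bad_src <- setdiff(edges$source, c(nodes, inputs))
  if (length(bad_src))
    stop("unknown edge source(s): ", paste(bad_src, collapse = ", "), call. = FALSE)
  bad_tgt <- setdiff(edges$target, nodes)
  if (length(bad_tgt))
    stop("edge target(s) must be nodes (inputs are never targets): ",
         paste(bad_tgt, collapse = ", "), call. = FALSE)
  if (anyDuplicated(edges))
    stop("duplicate (source, target, sign) edge", call. = FALSE)

  structure(list(nodes = nodes, edges = edges, inputs = inputs),
            class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat("Regulatory network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges,", length(x$inputs), "inputs\n")
  cat("  nodes: ", paste(x$nodes, collapse = ", "), "\n", sep = "")
  if (length(x$inputs))
    cat("  inputs: ", paste(x$inputs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' The built-in 13-node ageing network
#'
#' Constructs the canonical ageing gene regulatory network: the p53
#' DNA-damage-response core (p53, Mdm2, Wip1, ATM, p21, PTEN, AKT)
#' coupled to Rb-E2F cell-cycle control (Myc, E2F, RB, CycE, CycD) via
#' ARF and p21. Two constant inputs drive it: `Stress` (oxidative or
#' DNA-damaging stress, activating ATM) and `GS` (growth signals,
#' activating Myc and CycD). The network has 13 nodes and 32 signed
#' directed interactions, counting the three input edges.
#'
#' Node order is fixed to the model's equation order: p53, Mdm2, Wip1,
#' ATM, p21, PTEN, AKT, Myc, E2F, RB, CycE, CycD, ARF.
#'
#' @return A [grn_network()] with 13 nodes, 32 edges and inputs
#'   `Stress`, `GS`.
#' @export
ageing_network <- function() {
  e <- function(source, target, sign) data.frame(
    source = source, target = target, sign = sign,
    stringsAsFactors = FALSE)
  act <- function(sources, target)
    e(sources, target, "activation")
  inh <- function(sources, target)
    e(sources, target, "inhibition")
  edges <- rbind(
    act(c("ARF", "p53", "ATM"), "p53"), inh(c("Mdm2", "Wip1"), "p53"),
    act(c("p53", "AKT", "Wip1"), "Mdm2"), inh(c("ATM", "ARF"), "Mdm2"),
    act("p53", "Wip1"),
    act(c("ATM", "Stress"), "ATM"), inh("Wip1", "ATM"),
    act("p53", "p21"), inh("AKT", "p21"),
    act("p53", "PTEN"),
    inh("PTEN", "AKT"),
    act("GS", "Myc"),
    act(c("E2F", "Myc"), "E2F"), inh(c("p21", "RB"), "E2F"),
    act("p21", "RB"), inh(c("CycD", "CycE"), "RB"),
    act("E2F", "CycE"), inh("p21", "CycE"),
    act(c("Myc", "GS"), "CycD"), inh("p21", "CycD"),
    act("Myc", "ARF")
  )
  grn_network(
    nodes = c("p53", "Mdm2", "Wip1", "ATM", "p21", "PTEN", "AKT",
              "Myc", "E2F", "RB", "CycE", "CycD", "ARF"),
    edges = edges,
    inputs = c("Stress", "GS")
  )
}

#' Delete edges from a network
#'
#' Returns a copy of the network with the listed interactions removed;
#' the original is unchanged. This is the in-silico perturbation used to
#' model loss of regulation, e.g. p53 inactivation by deleting its
#' activation by ATM and by ARF.
#'
#' @param network a [grn_network()].
#' @param edges the edges to delete: either a data frame with columns
#'   `source`, `target`, `sign`, or a character vector of
#'   `"source:target:sign"` strings (sign may be abbreviated
#'   `act`/`inh`).
#' @return A new `grn_network` without the listed edges.
#' @examples
#' net <- delete_edges(ageing_network(),
#'                     c("ATM:p53:activation", "ARF:p53:activation"))
#' nrow(net$edges)  # 30
#' @export
delete_edges <- function(network, edges) {
  stopifnot(inherits(network, "grn_network"))
  edges <- as_edge_frame(edges)
  if (nrow(edges) == 0L) return(network)
  keys <- edge_keys(network$edges)
  for (i in seq_len(nrow(edges))) {
    k <- edge_keys(edges[i, ])
    hit <- match(k, keys)
    if (is.na(hit))
      stop("edge not present in network: ", k, call. = FALSE)
    keys <- keys[-hit]
    network$edges <- network$edges[-hit, , drop = FALSE]
  }
  rownames(network$edges) <- NULL
  network
}

as_edge_frame <- function(edges) {
  if (is.character(edges)) {
    if (length(edges) == 0L)
      return(data.frame(source = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE))
    parts <- strsplit(edges, ":", fixed = TRUE)
    if (any(lengths(parts) != 3L))
      stop("edge strings must look like 'source:target:sign'", call. = FALSE)
    edges <- data.frame(
      source = vapply(parts, `[`, "", 1L),
      target = vapply(parts, `[`, "", 2L),
      sign = vapply(parts, `[`, "", 3L),
      stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$sign %in% c("act", "+"), "activation",
                ifelse(edges$sign %in% c("inh", "-"), "inhibition",
                       edges$sign))
  edges
}

edge_keys <- function(edges) {
  paste(edges$source, edges$target, edges$sign, sep = ":")
}

# Incidence matrices of the compiled network: rows are nodes, columns the
# extended species (nodes then inputs). Mact[i, j] = 1 iff j activates i.
network_matrices <- function(network) {
  ext <- c(network$nodes, network$inputs)
  nn <- length(network$nodes)
  Mact <- matrix(0, nn, length(ext), dimnames = list(network$nodes, ext))
  Minh <- Mact
  act <- network$edges$sign == "activation"
  idx <- cbind(match(network$edges$target, network$nodes),
               match(network$edges$source, ext))
  Mact[idx[act, , drop = FALSE]] <- 1
  Minh[idx[!act, , drop = FALSE]] <- 1
  list(Mact = Mact, Minh = Minh)
}

#' Read or write a network edge list
#'
#' Networks are exchanged as tab-separated edge lists with a
#' `source  target  sign` header. Inputs are not part of the edge file;
#' they are declared separately (or inferred: any edge source that is
#' never a target is treated as an input by `read_network_tsv()` unless
#' `inputs` is given).
#'
#' @param network a [grn_network()].
#' @param file path of the TSV file.
#' @param nodes,inputs optional explicit node order and input set for
#'   the reader; by default nodes are all edge targets (in order of
#'   first appearance) plus non-target sources that are not inputs.
#' @return `read_network_tsv()` returns a [grn_network()];
#'   `write_network_tsv()` returns `file` invisibly.
#' @export
write_network_tsv <- function(network, file) {
  stopifnot(inherits(network, "grn_network"))
  utils::write.table(network$edges, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(file, nodes = NULL, inputs = NULL) {
  edges <- utils::read.table(file, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (is.null(inputs))
    inputs <- setdiff(unique(edges$source), unique(edges$target))
  if (is.null(nodes))
    nodes <- setdiff(unique(c(edges$target, edges$source)), inputs)
  grn_network(nodes, edges, inputs)
}
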