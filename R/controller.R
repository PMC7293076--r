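N_INPUTS <- 49L
N_HIDDEN <- 8L
N_OUTPUTS <- 2L
#' @rdname decodeGenome
#' @export
GENOME_LENGTH <- 410L  # 49*8 input->hidden + 9*2 (hidden + bias)->output

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Construct a genome
#'
#' A genome carries one or two gene vectors of length 410, each encoding the
#' connection weights of one perceptron network. Individuals with two
#' networks arise through the network-duplication operator; when two such
#' individuals are paired, each expresses a different copy (see
#' [assignRoles()]).
#'
#' @param networks A numeric vector of length 410, or a list of one or two
#'   such vectors.
#' @param lineage_id Identifier for checkpointing and provenance.
#' @return An object of class `Genome`.
#' @export
genome <- function(networks, lineage_id = "g0") {
  if (is.numeric(networks)) networks <- list(networks)
  if (!is.list(networks) || length(networks) < 1L || length(networks) > 2L)
    stop("a genome carries 1 or 2 networks", call. = FALSE)
  for (v in networks) {
    if (!is.numeric(v) || length(v) != GENOME_LENGTH)
      stop("each gene vector must have length ", GENOME_LENGTH, call. = FALSE)
    if (!all(is.finite(v)))
      stop("gene vectors must be finite", call. = FALSE)
  }
  structure(list(networks = lapply(networks, as.numeric),
                 lineage_id = as.character(lineage_id)),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("<Genome> %s: %d network(s) x %d genes\n",
              x$lineage_id, length(x$networks), GENOME_LENGTH))
  invisible(x)
}

#' Decode a gene vector into perceptron weights
#'
#' Fixed layout, input-major: gene `(i-1)*8 + j` is the weight from input
#' `i` (of 49) to hidden unit `j` (of 8); the last 18 genes fill the 9 x 2
#' `(hidden + hidden-layer bias) -> output` matrix, hidden-major. The layout
#' is stable across versions so that serialized genomes replay identically.
#'
#' @param gene_vector Numeric vector of length 410.
#' @return A list with `input_to_hidden` (49 x 8) and `hidden_to_output`
#'   (9 x 2); row 9 of the latter is the hidden-layer bias.
#' @export
decodeGenome <- function(gene_vector) {
  if (!is.numeric(gene_vector) || length(gene_vector) != GENOME_LENGTH)
    stop("gene vector must have length ", GENOME_LENGTH, call. = FALSE)
  list(input_to_hidden = matrix(gene_vector[1:392], nrow = N_INPUTS,
                                ncol = N_HIDDEN, byrow = TRUE),
       hidden_to_output = matrix(gene_vector[393:410], nrow = N_HIDDEN + 1L,
                                 ncol = N_OUTPUTS, byrow = TRUE))
}

#' @rdname decodeGenome
#' @param weights A list as returned by `decodeGenome()`.
#' @export
encodeWeights <- function(weights) {
  stopifnot(all(dim(weights$input_to_hidden) == c(N_INPUTS, N_HIDDEN)),
            all(dim(weights$hidden_to_output) == c(N_HIDDEN + 1L, N_OUTPUTS)))
  c(as.vector(t(weights$input_to_hidden)),
    as.vector(t(weights$hidden_to_output)))
}

#' Forward pass of the controller perceptron
#'
#' A fully connected multilayer perceptron with a single hidden layer of 8
#' units and logistic-sigmoid activations throughout: `hidden =
#' sigmoid(inputs %*% W1)`, `outputs = sigmoid(c(hidden, 1) %*% W2)`. The two
#' outputs are the wheel commands (0 = full backward, 1 = full forward).
#'
#' @param weights A decoded weight list ([decodeGenome()]) or a raw gene
#'   vector of length 410.
#' @param inputs Numeric vector of 49 input activations ([encodeInputs()]).
#' @return Length-2 numeric in (0, 1): left and right wheel commands.
#' @examples
#' forwardNetwork(rep(0, 410), rep(0, 49))  # all-zero weights -> (0.5, 0.5)
#' @export
forwardNetwork <- function(weights, inputs) {
  if (is.numeric(weights)) weights <- decodeGenome(weights)
  if (length(inputs) != N_INPUTS)
    stop("inputs must have length ", N_INPUTS, call. = FALSE)
  if (!all(is.finite(weights$input_to_hidden)) ||
      !all(is.finite(weights$hidden_to_output)))
    stop("non-finite weights", call. = FALSE)
  # Mirrors the compiled path's summation order exactly (two double-precision
  # accumulation chains over even/odd input positions, combined at the end).
  # Explicit loops rather than colSums(): R's colSums accumulates in extended
  # precision, which would not reproduce the compiled arithmetic bit for bit.
  w1 <- weights$input_to_hidden
  a0 <- numeric(N_HIDDEN)
  a1 <- numeric(N_HIDDEN)
  for (i in seq(1L, N_INPUTS - 2L, by = 2L)) {
    a0 <- a0 + inputs[i] * w1[i, ]
    a1 <- a1 + inputs[i + 1L] * w1[i + 1L, ]
  }
  a0 <- a0 + inputs[N_INPUTS] * w1[N_INPUTS, ]
  hidden <- sigmoid(a0 + a1)
  w2 <- weights$hidden_to_output
  s <- numeric(N_OUTPUTS)
  for (j in seq_len(N_HIDDEN)) s <- s + hidden[j] * w2[j, ]
  unname(sigmoid(s + w2[N_HIDDEN + 1L, ]))
}

#' Decide which network copy each pair member expresses
#'
#' When both individuals carry two networks, a fair coin decides which robot
#' expresses copy 1 while the other expresses copy 2 — the two robots always
#' express different copy indices, the substrate of the leader-follower
#' division of labor. A single-network individual expresses its only
#' network; a dual-network individual facing a single-network partner
#' expresses a uniformly chosen copy.
#'
#' @param genome_A,genome_B The two paired [genome()]s (robots A and B).
#' @return Integer vector of length 2: the copy index each robot expresses.
#' @export
assignRoles <- function(genome_A, genome_B) {
  nA <- length(genome_A$networks)
  nB <- length(genome_B$networks)
  if (nA == 2L && nB == 2L) {
    a <- if (runif(1) < 0.5) 1L else 2L
    c(a, 3L - a)
  } else {
    pick <- function(n) if (n == 1L) 1L else if (runif(1) < 0.5) 1L else 2L
    c(pick(nA), pick(nB))
  }
}
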