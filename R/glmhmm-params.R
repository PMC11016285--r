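#' Construct multinomial GLM-HMM parameters
#'
#' A K-state hidden Markov model whose per-state emission is a multinomial
#' logistic regression over the three choice categories `L`, `R`, `Nr`
#' (left lick, right lick, no response). The `Nr` category is the softmax
#' reference: its weights and bias are fixed at zero in every state, which
#' removes the usual softmax over-parameterization without changing any
#' emission probability.
#'
#' @param K number of hidden states.
#' @param weights numeric array `K x 3 x D` of per-state, per-category GLM
#'   weights on the stimulus input(s); column order `L`, `R`, `Nr`. The `Nr`
#'   slice must be zero. A `K x 3` matrix is accepted for `D = 1`.
#' @param biases numeric `K x 3` matrix of per-state, per-category biases;
#'   the `Nr` column must be zero.
#' @param transition `K x K` row-stochastic transition matrix.
#' @param init_prob length-`K` initial state distribution.
#' @return An object of class `glmhmm_params`.
#' @examples
#' p <- glmhmm_params(
#'   K = 1, weights = matrix(c(-4, 4, 0), 1), biases = matrix(c(1, 1, 0), 1),
#'   transition = matrix(1), init_prob = 1
#' )
#' emission_probs(p, 1, u = -1)
#' @export
glmhmm_params <- function(K, weights, biases, transition, init_prob) {
  K <- as.integer(K)
  abort_if(K < 1L, "K must be >= 1")
  if (is.matrix(weights)) weights <- array(weights, dim = c(dim(weights), 1L))
  abort_if(length(dim(weights)) != 3L || dim(weights)[1] != K ||
             dim(weights)[2] != 3L,
           "weights must be a K x 3 x D array (categories L, R, Nr)")
  biases <- as.matrix(biases)
  abort_if(!all(dim(biases) == c(K, 3L)), "biases must be a K x 3 matrix")
  transition <- as.matrix(transition)
  abort_if(!all(dim(transition) == c(K, K)), "transition must be K x K")
  abort_if(any(transition < 0) ||
             any(abs(rowSums(transition) - 1) > 1e-10),
           "transition matrix rows must be nonnegative and sum to 1")
  init_prob <- as.numeric(init_prob)
  abort_if(length(init_prob) != K || any(init_prob < 0) ||
             abs(sum(init_prob) - 1) > 1e-10,
           "init_prob must be a K-simplex vector")
  abort_if(any(weights[, 3L, ] != 0) || any(biases[, 3L] != 0),
           "reference category Nr must have zero weights and bias")
  dimnames(weights) <- list(NULL, CHOICE_LEVELS, NULL)
  colnames(biases) <- CHOICE_LEVELS
  structure(
    list(K = K, D = dim(weights)[3], weights = weights, biases = biases,
         transition = transition, init_prob = init_prob),
    class = "glmhmm_params"
  )
}

#' @export
print.glmhmm_params <- function(x, ...) {
  cat("Multinomial GLM-HMM parameters:", x$K, "state(s),",
      x$D, "input dimension(s)\n")
  cat("Transition diagonal:",
      paste(sprintf("%.3f", diag(x$transition)), collapse = " "), "\n")
  invisible(x)
}

#' Emission probabilities of one state
#'
#' Softmax of the per-category logits `w[k, c] . u + b[k, c]` — the
#' psychometric curve of state `k` evaluated at stimulus value `u`.
#'
#' @param params a [glmhmm_params] object.
#' @param k state index in `1..K`.
#' @param u stimulus input (length `D`).
#' @return Named probability vector over `L`, `R`, `Nr`.
#' @export
emission_probs <- function(params, k, u) {
  abort_if(!inherits(params, "glmhmm_params"), "params must be glmhmm_params")
  abort_if(k < 1 || k > params$K, "state index out of range")
  abort_if(!all(is.finite(u)) || length(u) != params$D,
           "u must be a finite length-D input")
  w_k <- matrix(params$weights[k, , ], nrow = 3L)  # 3 x D
  logits <- drop(w_k %*% u) + params$biases[k, ]
  p <- exp(logits - logsumexp(logits))
  p / sum(p)
}

# T x K matrix of log p(y_t | z_t = k, u_t) for one session
emission_loglik_matrix <- function(params, U, y_codes) {
  U <- as.matrix(U)
  T_n <- nrow(U)
  out <- matrix(0, T_n, params$K)
  for (k in seq_len(params$K)) {
    w_k <- matrix(params$weights[k, , ], nrow = 3L)      # 3 x D
    logits <- U %*% t(w_k) +
      matrix(params$biases[k, ], T_n, 3L, byrow = TRUE)  # T x 3
    m <- pmax(logits[, 1L], logits[, 2L], logits[, 3L])
    lse <- m + log(exp(logits[, 1L] - m) + exp(logits[, 2L] - m) +
                     exp(logits[, 3L] - m))
    out[, k] <- logits[cbind(seq_len(T_n), y_codes)] - lse
  }
  out
}

# extract inputs (T x D matrix) and choice codes from a trial table
session_design <- function(trials) {
  abort_if(!is.data.frame(trials) || nrow(trials) == 0L,
           "each session needs a nonempty trial table")
  abort_if(is.null(trials$stimulus_value) || is.null(trials$choice),
           "trial table must have stimulus_value and choice columns")
  abort_if(!all(is.finite(trials$stimulus_value)),
           "stimulus_value contains non-finite values")
  list(U = matrix(trials$stimulus_value, ncol = 1L),
       y = choice_codes(trials$choice))
}

#' Serialize GLM-HMM parameters to JSON
#'
#' Round-trips exactly through [params_from_json()].
#' @param params a [glmhmm_params] object.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
params_to_json <- function(params, path = NULL) {
  x <- list(K = params$K, D = params$D,
            weights = params$weights, biases = params$biases,
            transition = params$transition, init_prob = params$init_prob)
  js <- jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize GLM-HMM parameters from JSON
#' @param x JSON string or path to a JSON file written by [params_to_json()].
#' @return A [glmhmm_params] object.
#' @export
params_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  K <- as.integer(obj$K); D <- as.integer(obj$D)
  glmhmm_params(
    K = K,
    weights = array(unlist(obj$weights), dim = c(K, 3L, D)),
    biases = matrix(unlist(obj$biases), K, 3L),
    transition = matrix(unlist(obj$transition), K, K),
    init_prob = as.numeric(obj$init_prob)
  )
}
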