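# Language-model backend contract
#
# A backend is a list with class c("<specific>", "lm_backend") carrying
#   model_id             a label used in result tables
#   max_sequence_length  truncation limit for scoring
#   backend_tokenize()   the backend's own tokenizer
# and a token_logprobs() method returning log p(w_i | w_<i) for i = 1..n over
# the backend's tokenization, with a start-of-sequence context prepended so
# the first real token is conditionally scored.

#' Per-token conditional log-probabilities under a backend
#'
#' @param backend An \code{lm_backend}.
#' @param tokens Character vector of backend tokens (already tokenized).
#' @return Numeric vector of log-probabilities, one per token, each <= 0.
#' @export
token_logprobs <- function(backend, tokens) UseMethod("token_logprobs")

#' Tokenize text with a backend's own tokenizer
#' @param backend An \code{lm_backend}.
#' @param text A single string.
#' @return Character vector of backend tokens.
#' @export
backend_tokenize <- function(backend, text) {
  stopifnot(inherits(backend, "lm_backend"))
  backend$tokenizer(text)
}

#' @export
print.lm_backend <- function(x, ...) {
  cat(sprintf("<lm_backend:%s> %s (max_sequence_length %d)\n",
              class(x)[1], x$model_id, x$max_sequence_length))
  invisible(x)
}

new_backend <- function(subclass, model_id, max_sequence_length,
                        tokenizer = tokenize, ...) {
  structure(
    list(model_id = model_id,
         max_sequence_length = as.integer(max_sequence_length),
         tokenizer = tokenizer, ...),
    class = c(subclass, "lm_backend")
  )
}

#' Uniform reference backend
#'
#' Assigns every token probability 1/vocab_size regardless of context; the
#' perplexity of any nonempty sentence is exactly \code{vocab_size}. Used for
#' closed-form validation of the scoring path.
#'
#' @param vocab_size Positive integer vocabulary size.
#' @param model_id Label.
#' @param max_sequence_length Truncation limit.
#' @return An \code{lm_backend}.
#' @export
uniform_backend <- function(vocab_size, model_id = "uniform",
                            max_sequence_length = 1024L) {
  stopifnot(vocab_size >= 1)
  new_backend("uniform_backend", model_id, max_sequence_length,
              vocab_size = vocab_size)
}

#' @export
token_logprobs.uniform_backend <- function(backend, tokens) {
  rep(-log(backend$vocab_size), length(tokens))
}

#' Constant-probability reference backend
#'
#' Assigns every token a fixed probability p; perplexity is exactly 1/p.
#'
#' @param prob Probability in (0, 1].
#' @param model_id Label.
#' @param max_sequence_length Truncation limit.
#' @return An \code{lm_backend}.
#' @export
constant_backend <- function(prob, model_id = "constant",
                             max_sequence_length = 1024L) {
  stopifnot(prob > 0, prob <= 1)
  new_backend("constant_backend", model_id, max_sequence_length, prob = prob)
}

#' @export
token_logprobs.constant_backend <- function(backend, tokens) {
  rep(log(backend$prob), length(tokens))
}

# internal: map tokens to the closed vocabulary, unknowns to "<unk>"
.map_unk <- function(tokens, vocab_env) {
  ifelse(vapply(tokens, function(t) !is.null(vocab_env[[t]]), logical(1)),
         tokens, "<unk>")
}

#' Fit an additive-smoothed n-gram backend
#'
#' The reference language model: conditional probabilities are
#' additively smoothed n-gram estimates over the closed training vocabulary
#' plus an explicit unknown-token class, so every conditional distribution
#' sums to one over vocabulary + unk and unseen tokens keep perplexity
#' finite. Sequences are padded with n-1 start symbols so the first real
#' token is conditionally scored.
#'
#' @param training_texts Nonempty character vector of training documents.
#' @param order N-gram order, 1, 2 or 3.
#' @param smoothing Additive (Lidstone) constant, > 0. As it grows the model
#'   tends to the uniform distribution over vocabulary + unk.
#' @param model_id Label (default "ngram<order>").
#' @param max_sequence_length Truncation limit (default 1024).
#' @return An \code{lm_backend}.
#' @export
fit_ngram_backend <- function(training_texts, order = 2L, smoothing = 1,
                              model_id = paste0("ngram", order),
                              max_sequence_length = 1024L) {
  if (!order %in% 1:3) config_error("n-gram order must be 1, 2 or 3")
  if (!(is.numeric(smoothing) && smoothing > 0)) {
    config_error("smoothing must be > 0")
  }
  training_texts <- training_texts[nzchar(squish(training_texts))]
  if (length(training_texts) == 0L) config_error("no nonempty training text")
  docs <- tokenize(training_texts)
  if (length(training_texts) == 1L) docs <- list(docs)
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  if (length(vocab) == 0L) config_error("training text produced no tokens")
  vocab_env <- new.env(parent = emptyenv(), hash = TRUE)
  for (v in vocab) vocab_env[[v]] <- TRUE

  sep <- "\x1f"
  pad <- rep("<s>", order - 1L)
  ng_keys <- character(0)   # "<ctx>SEP<w>"
  ctx_keys <- character(0)  # "<ctx>"
  for (d in docs) {
    if (length(d) == 0L) next
    seqd <- c(pad, d)
    n <- length(d)
    if (order == 1L) {
      ctx <- rep("", n)
    } else {
      ctx <- vapply(seq_len(n), function(i) {
        paste(seqd[i:(i + order - 2L)], collapse = sep)
      }, character(1))
    }
    ng_keys <- c(ng_keys, paste(ctx, d, sep = sep))
    ctx_keys <- c(ctx_keys, ctx)
  }
  ng_tab <- table(ng_keys)
  ctx_tab <- table(ctx_keys)
  ng_names <- names(ng_tab); ng_counts <- as.numeric(ng_tab)
  ctx_names <- names(ctx_tab); ctx_counts <- as.numeric(ctx_tab)

  new_backend(
    "ngram_backend", model_id, max_sequence_length,
    order = as.integer(order), smoothing = smoothing,
    vocab = vocab, vocab_env = vocab_env, sep = sep,
    ng_names = ng_names, ng_counts = ng_counts,
    ctx_names = ctx_names, ctx_counts = ctx_counts
  )
}

# conditional probability lookup, vectorized over positions
.ngram_probs <- function(backend, ctx, w) {
  k <- backend$smoothing
  classes <- length(backend$vocab) + 1L  # vocabulary plus <unk>
  ng <- match(paste(ctx, w, sep = backend$sep), backend$ng_names)
  cc <- match(ctx, backend$ctx_names)
  num <- ifelse(is.na(ng), 0, backend$ng_counts[ng]) + k
  den <- ifelse(is.na(cc), 0, backend$ctx_counts[cc]) + k * classes
  num / den
}

#' @export
token_logprobs.ngram_backend <- function(backend, tokens) {
  if (length(tokens) == 0L) return(numeric(0))
  w <- .map_unk(tokens, backend$vocab_env)
  order <- backend$order
  seqd <- c(rep("<s>", order - 1L), w)
  n <- length(w)
  if (order == 1L) {
    ctx <- rep("", n)
  } else {
    ctx <- vapply(seq_len(n), function(i) {
      paste(seqd[i:(i + order - 2L)], collapse = backend$sep)
    }, character(1))
  }
  log(.ngram_probs(backend, ctx, w))
}

#' Conditional distribution of an n-gram backend for one context
#'
#' Returns the full next-token distribution over vocabulary + unk for a
#' given context; sums to one by construction (exposed for validation).
#'
#' @param backend An n-gram \code{lm_backend}.
#' @param context Character vector of order-1 preceding tokens ("<s>" pads).
#' @return Named numeric probability vector over c(vocab, "<unk>").
#' @export
ngram_conditional_distribution <- function(backend, context = character(0)) {
  stopifnot(inherits(backend, "ngram_backend"))
  order <- backend$order
  ctxtoks <- if (order == 1L) character(0) else {
    ctxtoks <- c(rep("<s>", order - 1L), .map_unk(context, backend$vocab_env))
    utils::tail(ctxtoks, order - 1L)
  }
  ctx <- if (order == 1L) "" else paste(ctxtoks, collapse = backend$sep)
  support <- c(backend$vocab, "<unk>")
  p <- .ngram_probs(backend, rep(ctx, length(support)), support)
  stats::setNames(p, support)
}

#' Adapter for causal transformer checkpoints
#'
#' Optional component wrapping a locally available causal language model and
#' its own tokenizer behind the backend contract. It requires a Python
#' runtime with the torch and transformers libraries reachable from R; when
#' that runtime is absent the constructor raises a classed environment error
#' with a remediation hint, and the rest of the package (n-gram and
#' reference backends, the full pipeline) is unaffected.
#'
#' @param checkpoint_ref Local path or hub identifier of the checkpoint.
#' @param max_sequence_length Truncation limit (e.g. 1024 for GPT-2-class
#'   models, 2048 for 7B-class models).
#' @param python Python executable to probe for the runtime.
#' @return An \code{lm_backend} (when the runtime is available).
#' @export
transformer_backend <- function(checkpoint_ref, max_sequence_length = 1024L,
                                python = Sys.which("python")) {
  stopifnot(is.character(checkpoint_ref), length(checkpoint_ref) == 1L)
  have_runtime <- nzchar(python) &&
    suppressWarnings(system2(python, c("-c", shQuote("import torch, transformers")),
                             stdout = FALSE, stderr = FALSE)) == 0L
  if (!have_runtime) {
    environment_error(paste0(
      "transformer backend requires a Python runtime with 'torch' and ",
      "'transformers' importable (checkpoint: ", checkpoint_ref, "). ",
      "Install them (pip install torch transformers) and ensure the ",
      "checkpoint is available locally, or use fit_ngram_backend() for a ",
      "self-contained reference model."
    ))
  }
  # runtime present: delegate tokenization + scoring to the bundled helper,
  # which prepends the model's BOS token and truncates to max_sequence_length
  helper <- system.file("python", "causal_lm_logprobs.py", package = "psefit")
  new_backend(
    "transformer_backend", basename(checkpoint_ref), max_sequence_length,
    tokenizer = function(text) {
      config_error("transformer backends tokenize internally; use compute_perplexity()")
    },
    checkpoint_ref = checkpoint_ref, python = python, helper = helper,
    score_text = function(text, max_len) {
      out <- system2(python, c(helper, shQuote(checkpoint_ref), max_len),
                     input = text, stdout = TRUE, stderr = FALSE)
      res <- jsonlite::fromJSON(paste(out, collapse = ""))
      if (!is.null(res$error)) scoring_error(res$error)
      list(logprobs = as.numeric(res$logprobs))
    }
  )
}
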