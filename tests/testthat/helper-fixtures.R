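# Shared fixtures and independent oracles, built in code at test time.

tiny_model <- function() {
  reference_ontology(list(
    reference_term("Demographics", value_domain("binary"),
                   description = "grouping class"),
    reference_term("gender",
                   value_domain("categorical", categories = c("female", "male")),
                   parent = "Demographics"),
    reference_term("age", value_domain("numeric", unit = "years",
                                       range = c(0, 120)),
                   parent = "Demographics"),
    reference_term("Laboratory", value_domain("binary")),
    reference_term("C4", value_domain("numeric", unit = "mg/dL",
                                      range = c(8, 60)),
                   parent = "Laboratory"),
    reference_term("Symptoms", value_domain("binary")),
    reference_term("lymphadenopathy", value_domain("binary"),
                   parent = "Symptoms"),
    reference_term("salivary gland swelling", value_domain("binary"),
                   parent = "Symptoms")
  ), name = "tiny")
}

# quadratic dynamic-programming Levenshtein distance, independent of adist
lev_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  d <- matrix(0L, m + 1, n + 1)
  d[, 1] <- 0:m; d[1, ] <- 0:n
  for (i in seq_len(m)) for (j in seq_len(n))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (A[i] != B[j]))
  d[m + 1, n + 1]
}

lexsim_oracle <- function(a, b) {
  ka <- normalize_key(a); kb <- normalize_key(b)
  if (!nzchar(ka) || !nzchar(kb)) return(0)
  1 - lev_oracle(ka, kb) / max(nchar(ka), nchar(kb))
}

# concordant-pair (Mann-Whitney) AUC with ties counted one half
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

random_string <- function(len) {
  paste(sample(c(letters[1:6], " ", "-"), len, replace = TRUE), collapse = "")
}

# small harmonized-style space for the federated unit tests
toy_space <- function(n, seed, shift = 2) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.2)
  data.frame(
    lymphoma = y,
    age = round(rnorm(n, 55, 10)),
    gender = sample(c("female", "male"), n, replace = TRUE, prob = c(0.8, 0.2)),
    marker = rnorm(n, mean = shift * y),
    noise = rnorm(n),
    check.names = FALSE
  )
}

encode_space <- function(spaces, ref, cols = NULL) {
  if (is.null(cols)) cols <- setdiff(names(ref), "lymphoma")
  enc <- cohortharmony:::build_encoder(ref, cols)
  lapply(spaces, function(s)
    list(x = cohortharmony:::apply_encoder(enc, s),
         y = as.numeric(s$lymphoma)))
}
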