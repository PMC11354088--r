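# small fixtures built in code

tiny_registry <- function(p = 4L, directions = rep("HIGH_GOOD", p),
                          domains = NULL) {
  if (is.null(domains)) domains <- bric_domains[(seq_len(p) - 1L) %% 6L + 1L]
  cri_registry(data.frame(
    id = sprintf("x%02d", seq_len(p)),
    name = sprintf("fixture %d", seq_len(p)),
    theme = "Synthetic", bric_domain = domains, direction = directions,
    source = "fixture", year = "n/a", stringsAsFactors = FALSE))
}

tiny_table <- function(values, directions = NULL, region = NULL) {
  p <- ncol(values)
  n <- nrow(values)
  if (is.null(directions)) directions <- rep("HIGH_GOOD", p)
  reg <- tiny_registry(p, directions)
  colnames(values) <- reg$id
  areas <- data.frame(
    area_id = sprintf("A%03d", seq_len(n)),
    region = if (is.null(region)) english_regions[(seq_len(n) - 1L) %% 9L + 1L] else region,
    coastal = rep(c(TRUE, FALSE), length.out = n),
    rurality = rurality_levels[(seq_len(n) - 1L) %% 3L + 1L],
    population = rep(100000, n),
    peer_group = paste0("PG", (seq_len(n) - 1L) %% 3L + 1L),
    stringsAsFactors = FALSE)
  area_table(values, areas, reg)
}

# a well-conditioned correlation matrix with one strong block
block_corr_4 <- function() {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.8
  R[3, 4] <- R[4, 3] <- 0.3
  R[1, 3] <- R[3, 1] <- 0.1
  R[1, 4] <- R[4, 1] <- 0.1
  R[2, 3] <- R[3, 2] <- 0.1
  R[2, 4] <- R[4, 2] <- 0.1
  R
}

# default synthetic dataset shared by the slower recovery tests
default_synthesis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synth_generate(synth_config(seed = 101L))
    cache
  }
})
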