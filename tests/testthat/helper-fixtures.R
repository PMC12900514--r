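# shared in-code fixtures

# worked toy model: L = 3, tau = 1, kappa = ln 2  =>  p = 0.5 at every site
toy_model <- function() pause_termination_model(tau = rep(1, 3), kappa = log(2))

random_model <- function(L = sample(5:500, 1)) {
  pause_termination_model(
    tau = stats::runif(L, 0.1, 10),
    kappa = stats::runif(1, 0, 0.5),
    alpha = stats::runif(1, 0.5, 2)
  )
}

make_reads <- function(start, end, umi, strand = "+", replicate = "rep1",
                       condition = "wt") {
  n <- length(start)
  data.frame(start = as.integer(start), end = as.integer(end),
             strand = rep_len(strand, n), umi = rep_len(as.character(umi), n),
             replicate = rep_len(replicate, n),
             condition = rep_len(condition, n), stringsAsFactors = FALSE)
}

# read sets with injected duplication over a small key space
random_read_set <- function(n_max = 200) {
  n <- sample.int(n_max, 1)
  end <- sample.int(50, n, replace = TRUE)
  start <- pmax(1L, end - sample.int(20, n, replace = TRUE))
  make_reads(start, end,
             umi = sample(c("AA", "AC", "CA", "CC"), n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE))
}

# profile with given counts vector, for aggregate/compare tests
profile_from_counts <- function(counts, condition = "wt", replicate = "rep1") {
  reads <- make_reads(rep(1L, sum(counts)),
                      rep(seq_along(counts), counts),
                      umi = "AAAAA", condition = condition,
                      replicate = replicate)
  coverage_3p(reads, length(counts), condition = condition,
              replicate = replicate)
}

fake_aggregate <- function(mean, min = mean, max = mean, condition = "a") {
  structure(list(condition = condition, n_replicates = 3L,
                 mean = mean, min = min, max = max),
            class = "replicate_aggregate")
}
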