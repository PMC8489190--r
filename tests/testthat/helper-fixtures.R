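# Shared fixtures and independent oracles, all built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 vector as 1:n; pick from lo..hi safely
pick_int <- function(lo, hi) if (lo >= hi) as.integer(lo) else sample(lo:hi, 1L)

random_scheme <- function(heights) vapply(heights, function(h)
  pick_int(0L, h), integer(1))

lift_scheme <- function(g, heights) vapply(seq_along(g), function(i)
  pick_int(g[i], heights[i]), integer(1))

toy_ctx <- function(privacy = k_anonymity(3L)) {
  toy <- toy8()
  anon_context(toy$data, toy$hierarchies, privacy)
}

# 20-record instance whose global optimum must suppress a 4-record outlier
# group that local recoding rescues at a coarser scheme: 16 records in four
# size-4 classes at level (0,0) plus 4 mutually distinct outliers that only
# merge into one class at scheme (1,1).
local_gain_fixture <- function() {
  a_h <- hierarchy(cbind(
    as.character(1:8),
    rep(c("[1-2]", "[3-4]", "[5-6]", "[7-8]"), each = 2),
    rep(c("[1-4]", "[5-8]"), each = 4),
    rep("*", 8)), "A")
  b_h <- hierarchy(cbind(c("M", "F"), c("*", "*")), "B")
  data <- data.frame(
    A = c(rep(c("1", "2", "3", "4"), each = 4), "7", "7", "8", "8"),
    B = c(rep(c("M", "F", "M", "F"), each = 4), "M", "F", "M", "F"),
    stringsAsFactors = FALSE)
  list(data = anon_dataset(data, c(A = "quasi_identifying",
                                   B = "quasi_identifying")),
       hierarchies = list(A = a_h, B = b_h))
}

# Sequential (Chinese-restaurant) sampler of a PD(alpha, theta) partition —
# the simulation oracle for the Pitman moment fit, independent of the
# closed-form expectations used by the fit itself.
crp_sample <- function(theta, alpha, n) {
  counts <- integer(0)
  for (i in seq_len(n)) {
    k <- length(counts)
    j <- sample.int(k + 1L, 1L, prob = c(counts - alpha, theta + alpha * k))
    if (j > k) counts <- c(counts, 1L) else counts[j] <- counts[j] + 1L
  }
  counts
}

# Random small anonymization instance for property tests.
random_instance <- function(seed, max_attrs = 5L, max_height = 3L,
                            max_records = 200L, k_choices = c(2L, 3L, 5L)) {
  set.seed(seed)
  m <- sample(2:max_attrs, 1)
  doms <- sample(c(2, 3, 4, 6, 8), m, replace = TRUE)
  doms <- pmin(doms, 2^max_height)
  n <- sample(30:max_records, 1)
  syn <- generate_dataset(n, lapply(doms, function(d)
    list(domain_size = d, distribution = "zipf")), seed = seed + 7L)
  k <- sample(k_choices, 1)
  anon_context(syn$data, syn$hierarchies, k_anonymity(k))
}

write_toy_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- toy8()
  data_path <- file.path(dir, "toy.csv")
  write_dataset(toy$data, data_path)
  age_path <- file.path(dir, "age.csv")
  sex_path <- file.path(dir, "sex.csv")
  write_hierarchy(toy$hierarchies$age, age_path)
  write_hierarchy(toy$hierarchies$sex, sex_path)
  list(data = data_path, age = age_path, sex = sex_path)
}

write_toy_config <- function(dir, k = 3L, algorithm = "exhaustive",
                             extra = list()) {
  paths <- write_toy_files(dir)
  cfg <- c(list(
    input = paths$data,
    quasi_identifiers = list(age = paths$age, sex = paths$sex),
    privacy = list(model = "k_anonymity", k = k),
    algorithm = algorithm,
    output = file.path(dir, "out.csv"),
    report = file.path(dir, "report.yaml")), extra)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
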