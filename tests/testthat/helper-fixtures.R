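# Fixtures are built in code; nothing is read from disk except what a test
# itself writes to tempfile().

toy_counts <- function() {
  m <- matrix(c(5L, 0L, 3L, 2L,
                1L, 4L, 0L, 5L,
                2L, 2L, 2L, 4L), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("otu1", "otu2", "otu3", "otu4")))
  m
}

toy_taxonomy <- function() {
  c(otu1 = "Bacteria;Cyanobacteria",
    otu2 = "Bacteria;Proteobacteria;Alphaproteobacteria",
    otu3 = "Bacteria;Cyanobacteria",
    otu4 = "Unclassified")
}

toy_table <- function() otu_table(toy_counts(), toy_taxonomy())

# write the canonical OTUs-as-rows TSV layout
write_otu_tsv <- function(counts, taxonomy, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(otu_id = colnames(counts), t(counts),
                   taxonomy = taxonomy[colnames(counts)],
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_metadata <- function(n = 13, months = rep("May", n)) {
  df <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    month = months,
    latitude = 56 + 0.05 * seq_len(n),
    longitude = 16.5 + 0.01 * seq_len(n),
    salinity = 7 - 0.1 * seq_len(n),
    temperature = 10 + 0.5 * seq_len(n),
    chla = 3 + 0.1 * seq_len(n),
    nh4 = 0.5 + 0.01 * seq_len(n),
    no3 = 2 - 0.05 * seq_len(n),
    po4 = 0.6 + 0.005 * seq_len(n),
    sio4 = 12 + 0.2 * seq_len(n),
    stringsAsFactors = FALSE)
  sample_metadata(df, c("salinity", "temperature", "chla", "nh4", "no3",
                        "po4", "sio4"))
}

tree4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# independent brute-force Bray-Curtis (double loop over the formula)
bray_oracle <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  }
  d
}

# small random dataset for association tests: points in R^2 per matrix
random_dist <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n), n, 2,
              dimnames = list(paste0("s", seq_len(n)), NULL))
  dist_matrix(dist(x))
}

default_env_vars <- function() c("salinity", "temperature", "chla", "nh4",
                                 "no3", "po4", "sio4")
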