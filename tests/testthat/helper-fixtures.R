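# shared fixture builders; everything is generated in code at test time

write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# tiny three-species stigma-load table with one empty stigma
toy_loads <- function() {
  tibble::tibble(
    stigma_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    species = c("A", "A", "A", "B", "B", "C"),
    cp = c(10L, 20L, 30L, 5L, 0L, 8L),
    hp = c(2L, 0L, 4L, 0L, 0L, 1L),
    hp_diversity = c(1L, 0L, 2L, 0L, 0L, 1L)
  )
}

as_network <- function(M, plants = NULL, polls = NULL) {
  if (is.null(plants)) plants <- sprintf("P%d", seq_len(nrow(M)))
  if (is.null(polls)) polls <- sprintf("A%d", seq_len(ncol(M)))
  dimnames(M) <- list(plants, polls)
  structure(list(matrix = M, binarized = FALSE), class = "bipartite_network")
}

# all length-1..max_dim marginal vectors with entries 1..max_entry and
# bounded total
marginal_vectors <- function(max_dim = 3, max_entry = 6, max_total = 12) {
  out <- list()
  for (k in seq_len(max_dim)) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(max_entry)), k)))
    for (i in seq_len(nrow(grid))) {
      v <- as.numeric(grid[i, ])
      if (sum(v) <= max_total) out[[length(out) + 1]] <- v
    }
  }
  out
}

# random edge list in which every named pollinator and plant interacts
random_edges <- function(n_plants, n_polls, n_extra = 20) {
  plants <- sprintf("p%02d", seq_len(n_plants))
  polls <- sprintf("a%02d", seq_len(n_polls))
  base <- tibble::tibble(
    plant = sample(plants, max(n_plants, n_polls), replace = TRUE),
    pollinator = polls[rep_len(seq_len(n_polls), max(n_plants, n_polls))],
    weight = sample(1:5, max(n_plants, n_polls), replace = TRUE)
  )
  base$plant[seq_len(n_plants)] <- plants  # every plant appears too
  extra <- tibble::tibble(
    plant = sample(plants, n_extra, replace = TRUE),
    pollinator = sample(polls, n_extra, replace = TRUE),
    weight = sample(1:5, n_extra, replace = TRUE)
  )
  dplyr::bind_rows(base, extra)
}
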