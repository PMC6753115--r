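# Shared fixtures, generated in code.

# A library of random-texture cubes with a centred cubic "structure"
# label, for engine-level tests where realistic anatomy is irrelevant.
tiny_library <- function(n_cn = 2, n_ad = 2, n = 16, seed = 1,
                         sd_noise = 10) {
  set.seed(seed)
  tags <- c(rep(1L, n_cn), rep(2L, n_ad))
  lab <- array(0L, c(n, n, n))
  core <- seq(n %/% 4 + 1, n - n %/% 4)
  lab[core, core, core] <- 1L
  templates <- lapply(seq_along(tags), function(t) {
    base <- array(100, c(n, n, n))
    base[lab == 1L] <- 140
    list(id = sprintf("t%d", t),
         intensity = as_volume(base + array(rnorm(n^3, 0, sd_noise),
                                            c(n, n, n))),
         labels = lab, brain = array(TRUE, c(n, n, n)),
         group_tag = tags[t], severity = ifelse(tags[t] == 1L, 0, 1))
  })
  structure(list(templates = templates,
                 meta = data.frame(template_id = seq_along(tags),
                                   group_tag = tags, severity = 0),
                 spec = phantom_spec()),
            class = "template_library")
}

retag <- function(library, tags) {
  for (i in seq_along(library$templates))
    library$templates[[i]]$group_tag <- as.integer(tags[i])
  library$meta$group_tag <- as.integer(tags)
  library
}

spec32 <- function(...) phantom_spec(grid_extent = 32L, ...)

cfg32 <- function(...) patch_config(patch_radius = 2L, search_radius = 1L, ...)

random_voxels <- function(n, d, margin = 0) {
  cbind(sample((1 + margin):(d[1] - margin), n, TRUE),
        sample((1 + margin):(d[2] - margin), n, TRUE),
        sample((1 + margin):(d[3] - margin), n, TRUE))
}
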