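# Shared fixtures, built once per test run and cached across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_model <- function() cached("small_model", demo_head_model("small"))

scaled_montage <- function(s = 0.55) {
  co <- rat_montage_12()
  co$x <- co$x * s
  co$y <- co$y * s
  co
}

# A plain labeled cube, built directly (side mm, voxel mm).
cube_volume <- function(side = 10, voxel = 0.5) {
  n <- round(side / voxel)
  structure(list(labels = array(1L, c(n, n, n)), voxel = voxel,
                 origin = rep(voxel / 2, 3),
                 regions = tibble::tibble(label = 1L, name = "cube",
                                          include = TRUE),
                 include = 1L),
            class = "labeled_volume")
}

# Tiny coarse sphere mesh for depth/oracle smoke tests.
coarse_sphere <- function() cached("coarse_sphere",
                                   sphere_mesh(radius = 10, subdiv = 3,
                                               layers = 8))

# Distance from a map argmax to the nearest of a set of dipoles (mm).
argmax_dist <- function(values, grid, dipoles) {
  am <- grid$pos[which.max(values), ]
  min(sqrt(rowSums(sweep(matrix(grid$pos[dipoles, ], ncol = 3), 2, am)^2)))
}

assr_fixture <- function() {
  cached("assr_ds", {
    mdl <- small_model()
    proto <- assr_protocol(n_subjects = 2, seed = 11)
    list(mdl = mdl, proto = proto,
         ds = generate_assr_dataset(mdl$lf, proto))
  })
}

phantom_fixture <- function() {
  cached("phantom_pair", {
    mdl <- small_model()
    cfg <- phantom_config(duration = 10, seed = 3, gen_edge = 0.75)
    list(mdl = mdl, cfg = cfg,
         pair = build_mismatched_pair(mdl$vol, scaled_montage(), mdl$grid,
                                      cfg),
         dip = phantom_dipoles(mdl$grid))
  })
}
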