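# Shared fixtures, built once per test run.

the_fixtures <- new.env()

test_model <- function() {
  if (is.null(the_fixtures$model))
    the_fixtures$model <- build_synthetic_model(2500, 5, seed = 42)
  the_fixtures$model
}

# frontal camera centred in a W x W image, scale s pixels per model unit
frontal_camera <- function(W = 96, s = NULL) {
  if (is.null(s)) s <- 0.62 * W / 160
  affine_camera(rbind(c(s, 0, 0, W / 2),
                      c(0, -s, 0, W * 0.52),
                      c(0, 0, 0, 1)))
}

random_affine_camera <- function() {
  affine_camera(rbind(matrix(stats::rnorm(8), 2, 4), c(0, 0, 0, 1)))
}

small_sim_config <- function(...) {
  defaults <- list(participants_per_grade = c(2, 2, 2, 2, 2, 2),
                   frames_per_patient = 12,
                   image_size = c(96, 96),
                   model_vertices = 2500, model_components = 5,
                   master_seed = 7L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

test_patient <- function() {
  if (is.null(the_fixtures$patient)) {
    cfg <- small_sim_config()
    the_fixtures$patient_config <- cfg
    the_fixtures$patient <- simulate_patient(test_model(), "P001", 3L, cfg,
                                             seed = 123L)
  }
  the_fixtures$patient
}

with_seed <- flowgrade:::with_seed
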