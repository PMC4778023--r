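# full-resolution SD-I benchmark system, built once per test run
sdI_system <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      layout <- make_layout("SD-I", pitch = 1)
      grid <- default_grid("SD-I", voxel_size = 0.2)
      A <- build_sensing_matrix(layout, grid)
      cache <<- list(
        layout = layout, grid = grid, A = A,
        x_true = voxelize_scene(scene_library("fig1_disk"), grid))
    }
    cache
  }
})
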