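# Small, fast protocol with a smooth (low-beta) tracer: few angles and
# steps, 2 drive periods per step. Used wherever full-physics brute force
# must stay cheap; the low beta keeps the kernel well resolved so the fast
# and direct paths can be compared at tight tolerance.
smooth_protocol <- function(n_projections = 4, n_points = 9, fov = 0.2, ...) {
  scan_protocol(
    drive_amplitude = 25e-3, drive_frequency = 1e4, Gx = 1.5, fov = fov,
    n_projections = n_projections, n_points = n_points, sample_rate = 2e5,
    periods_per_point = 2, spion = spion_model(128, 80),
    receive = uniform_receive(9.26e-5), ...
  )
}
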