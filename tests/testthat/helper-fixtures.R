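# Shared fixture builders; everything is generated in code at test time.

fixture_two_prisms <- function() {
  big <- prism_mesh("y", c(0, 0.5), 0.1, 32L, center = c(0.5, 0, 0))
  small <- prism_mesh("y", c(0, 0.5), 0.05, 32L, center = c(-0.5, 0, 0))
  anthrofit:::merge_meshes(list(big, small))$mesh
}

rotate_about_y <- function(mesh, angle) {
  R <- rbind(c(cos(angle), 0, sin(angle)),
             c(0, 1, 0),
             c(-sin(angle), 0, cos(angle)))
  anthro_mesh(mesh$vertices %*% t(R), mesh$faces, mesh$up_axis)
}

translate_mesh <- function(mesh, by) {
  anthro_mesh(mesh$vertices + matrix(by, nrow(mesh$vertices), 3,
                                     byrow = TRUE),
              mesh$faces, mesh$up_axis)
}

# pseudoinverse normal-equations oracle for OLS (independent of qr path)
ols_pinv_oracle <- function(X, y) as.vector(MASS::ginv(t(X) %*% X) %*% t(X) %*% y)
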