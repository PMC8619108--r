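#!/usr/bin/env Rscript
# Toy-scale detector training smoke run (kept out of the default test suite
# because of its runtime): trains the 25-layer encoder-decoder on 200
# synthetic 64x64 crops for 30 epochs and reports the loss trajectory plus
# the architecture audit. A narrow width (base_filters = 2) keeps the run
# desk-scale; the layer topology is unchanged.
#
# Usage: Rscript scripts/detector_smoke.R [--seed <int>]

suppressMessages(library(pigtrackr))
args <- commandArgs(trailingOnly = TRUE)
i <- which(args == "--seed")
seed <- if (length(i) && i < length(args)) as.integer(args[i + 1]) else 1L

side <- 64
set.seed(seed)
make_pair <- function() {
  # one large pig, fixed pose family: centred body, jittered position/angle
  cx <- runif(1, 24, 40); cy <- runif(1, 24, 40); th <- runif(1, -pi, pi)
  L <- 28
  poses <- data.frame(x_shoulder = cx + L / 2 * cos(th),
                      y_shoulder = cy + L / 2 * sin(th),
                      x_tail = cx - L / 2 * cos(th),
                      y_tail = cy - L / 2 * sin(th))
  poses$x_lear <- poses$x_shoulder + 5 * cos(th - pi / 4)
  poses$y_lear <- poses$y_shoulder + 5 * sin(th - pi / 4)
  poses$x_rear <- poses$x_shoulder + 5 * cos(th + pi / 4)
  poses$y_rear <- poses$y_shoulder + 5 * sin(th + pi / 4)
  poses[] <- lapply(poses, function(v) pmin(pmax(v, 1), side - 2))
  st <- encode_poses(poses, side, side, marker_radius = 2, line_width = 2)
  img <- matrix(runif(side^2, 0, 0.15), side, side) +
    0.8 * unclass(st)[, , 5] + 0.4 * unclass(st)[, , 3]
  list(image = pmin(img, 1), stack = st)
}
pairs <- replicate(200, make_pair(), simplify = FALSE)

model <- build_detector(net_spec(c(side, side, 1), base_filters = 2),
                        seed = seed)
print(model)
audit <- network_audit(model)
stopifnot(audit$n_conv == 25, audit$latent_scale == 1 / 16,
          audit$out_channels == 7, audit$out_activation == "sigmoid")

t0 <- Sys.time()
res <- train_toy(model, lapply(pairs, `[[`, "image"),
                 lapply(pairs, `[[`, "stack"), epochs = 30, seed = seed)
dt <- as.numeric(Sys.time() - t0, units = "mins")

print(res$history)
cat(sprintf("trained 30 epochs in %.1f min\n", dt))
cat(sprintf("training loss %.4f -> %.4f (%s)\n",
            res$history$train_loss[1], res$history$train_loss[30],
            if (res$history$train_loss[30] < res$history$train_loss[1])
              "decreased" else "NOT decreased"))
stopifnot(res$history$train_loss[30] < res$history$train_loss[1])
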