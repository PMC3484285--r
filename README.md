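# flowgrid

Can optic flow alone tell a rat where it is? `flowgrid` is an R package
that models the full chain from visual motion to grid-cell firing for a
rat foraging on a circular platform: analytic spherical-camera optic flow
along a (synthetic or recorded) trajectory, Gaussian sensing noise, a
biologically motivated template decoder for linear and rotational
self-motion, path integration with an optional periodic reset standing in
for non-visual cues, a velocity-controlled oscillatory-interference model
of grid-cell spiking, and the standard rate-map analyses (smoothed
occupancy-normalised maps, spatial autocorrelograms, gridness scores,
k-means grid-spacing estimates).

It is aimed at computational neuroscientists studying spatial navigation
who want a reproducible, tested implementation of a flow-driven
path-integration pipeline — either to run the model end to end or to use
individual stages (the flow model, the decoder, the scoring tools) on
their own.

## The model in brief

Per pixel $(\theta, \phi)$ of a spherical camera at height $h$ with tilt
$\gamma$, planar self-motion $(v_z, \omega_y)$ over a ground plane induces
the constrained image motion

$$\dot{\vec\psi} = \tfrac{1}{h}\,\vec a(\theta,\phi,\gamma)\, v_z
  + \vec b(\theta,\phi,\gamma)\,\omega_y ,$$

where the known eye height resolves the speed/depth scaling invariance.
Sensed flow is this field plus i.i.d. Gaussian noise. Decoding is by
Gaussian-tuned template matching: projecting on $\vec b^\perp$ annihilates
the rotational term and yields a match profile over 117 sampled speeds;
the winning speed then constrains a second profile over 451 sampled yaw
rates; both are read out by a local vector sum (2 % window around the
peak). Decoded velocities are Euler-integrated and drive three dendritic
oscillators along basis directions 0°/120°/240°:

$$\mathrm{spike}(t) = 1 \iff \prod_{k=1}^{3}\Big[\cos(\omega t) +
 \cos\big(\omega t + \omega\beta \textstyle\int_0^t \vec v_{2D}\!\cdot\!
 \vec b_k\, ds\big)\Big] > \Theta ,$$

which fires on a hexagonal lattice with spacing
$G = 2/(\sqrt3\,\beta f) \approx 41$ cm at $f = 7.38$ Hz,
$\beta = 0.00385$ s/cm.

## A worked example

```r
library(flowgrid)
run <- run_pipeline(duration = 1080, seed = 11, sigma_flow = 12.5,
                    t_reset = 1)
print(run)
#> <flowgrid_run> 1080 s trajectory, sigma_flow = 12.5, gamma = 0 deg, t_reset = 1 min
#>   mean position error 0.64 cm, mean bearing error 0.63 deg
#>   2702 spikes, grid score 1.93, measured spacing 39.5 cm (theory 40.6 cm)
```

That is: over an 18-minute synthetic foraging session with moderate flow
noise and a 1-minute reset, integrating the decoded velocities tracks the
true position to well under a centimetre on average; the resulting spike
pattern is strongly hexagonal (gridness 1.93 on the [-2, 2] scale, where
anything above 1 is grid-like), and the spacing measured by clustering
the spikes agrees with the closed-form prediction of the oscillator
parameters to within a few percent.

Individual stages are ordinary functions, e.g.

```r
g  <- build_sensor_grid(camera_config())
fl <- image_motion_curvilinear(g, plane_depth(g, 3.5, 0), v_z = 20,
                               omega_y = 100)
estimate_self_motion(add_flow_noise(fl, noise_config(25)),
                     template_bank())
```

A thin command-line front end with `simulate-trajectory`, `estimate`,
`grid`, `score` and `sweep` subcommands is installed under
`inst/cli/flowgrid`.

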