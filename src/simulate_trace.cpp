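#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin dynamics of a trapped bead driven by a motor with a
// linear force-velocity law.  States: 0 unbound, 1 moving, 2 paused,
// 3 stalled.  The bead coordinate is x (nm, displacement from trap centre);
// the motor attachment coordinate is m.  While bound, the bead fluctuates
// about m with the trap stiffness (rigid motor-bead linkage: bead force =
// trap force = motor load); the motor load is the quasi-static trap force
// k*m, so that bead thermal noise does not rectify motor stepping.
//
// The stall state (motor frozen, exponential detachment dwell) is entered
// when k*m reaches stall_entry_fraction * stall_force; the linear FV law
// approaches the stall force only asymptotically, so a finite entry
// threshold is required.  Pauses are force-gated: entry hazard is
// pause_entry_rate * clamp(k*m / stall_force, 0, 1).

// [[Rcpp::export]]
List sim_trap_trace_cpp(double k, double drag, double kBT,
                        double v0, double Fs,
                        double detach_rate, double pause_entry_rate,
                        double pause_exit_rate, double pause_exit_detach_prob,
                        double reattach_rate,
                        double sample_rate, double duration,
                        double dt, double stall_entry_fraction) {
  const int block = (int) std::lround(1.0 / (sample_rate * dt));
  const int n_out = (int) std::floor(duration * sample_rate);
  const double relax = k / drag;             // 1 / relaxation time
  const double noise_amp = std::sqrt(2.0 * kBT * dt / drag);
  const double trigger = stall_entry_fraction * Fs;

  NumericVector force(n_out);
  std::vector<double> gt_start, gt_end, gt_level;
  std::vector<int> gt_kind;                   // 0 unbound, 1 moving, 2 pause, 3 stall

  int state = 0;                              // start unbound
  double x = 0.0, m = 0.0;
  double seg_t0 = 0.0;
  int seg_kind = 0;
  double seg_level = 0.0;

  RNGScope scope;
  long step = 0;
  for (int i = 0; i < n_out; ++i) {
    double acc = 0.0;
    for (int b = 0; b < block; ++b, ++step) {
      double t = step * dt;
      double noise = (kBT > 0.0) ? noise_amp * norm_rand() : 0.0;
      int new_state = state;
      switch (state) {
      case 0: {                               // unbound: OU about trap centre
        x += -relax * x * dt + noise;
        if (reattach_rate > 0.0 && unif_rand() < reattach_rate * dt) {
          new_state = 1;
          m = x;                              // motor engages at bead position
        }
        break;
      }
      case 1: {                               // moving
        double Fm = k * m;
        double v = v0 * (1.0 - Fm / Fs);
        if (v < 0.0) v = 0.0;
        if (v > v0) v = v0;
        m += v * dt;
        x += (-relax * (x - m)) * dt + noise;
        Fm = k * m;
        if (Fm >= trigger) {
          new_state = 3;
        } else if (pause_entry_rate > 0.0) {
          double gate = Fm / Fs;
          if (gate < 0.0) gate = 0.0;
          if (gate > 1.0) gate = 1.0;
          if (unif_rand() < pause_entry_rate * gate * dt) new_state = 2;
        }
        break;
      }
      case 2: {                               // paused: motor frozen
        x += (-relax * (x - m)) * dt + noise;
        if (unif_rand() < pause_exit_rate * dt) {
          new_state = (unif_rand() < pause_exit_detach_prob) ? 0 : 1;
        }
        break;
      }
      case 3: {                               // stalled: motor frozen
        x += (-relax * (x - m)) * dt + noise;
        if (detach_rate > 0.0 && unif_rand() < detach_rate * dt) new_state = 0;
        break;
      }
      }
      if (new_state != state) {
        gt_start.push_back(seg_t0);
        gt_end.push_back(t + dt);
        gt_kind.push_back(seg_kind);
        gt_level.push_back(seg_level);
        seg_t0 = t + dt;
        seg_kind = new_state;
        seg_level = (new_state == 0) ? 0.0 : k * m;
        if (new_state == 0) m = 0.0;          // link force reset; bead relaxes
        state = new_state;
      }
      acc += k * x;
    }
    force[i] = acc / block;
  }
  // close the final segment
  gt_start.push_back(seg_t0);
  gt_end.push_back(n_out * block * dt);
  gt_kind.push_back(seg_kind);
  gt_level.push_back(seg_level);

  return List::create(_["force"] = force,
                      _["gt_start"] = wrap(gt_start),
                      _["gt_end"] = wrap(gt_end),
                      _["gt_kind"] = wrap(gt_kind),
                      _["gt_level"] = wrap(gt_level));
}
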