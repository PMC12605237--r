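// Agent-based open-field trajectory simulator: Ornstein-Uhlenbeck speed,
// wrapped-normal heading noise, wall steering, explicit rearing episodes,
// and a three-state social automaton (roam / approach-and-contact /
// disengage) per animal. Driven by the R RNG so that set.seed() in R makes
// the output fully deterministic.
#include <Rcpp.h>
using namespace Rcpp;

static inline double wrap_pi(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a <= -M_PI) a += 2.0 * M_PI;
  return a;
}

enum State { ROAM = 0, APPROACH = 1, CONTACT = 2, BREAK = 3, FOLLOW = 4,
             AVOID = 5 };

struct Mouse {
  // kinematic state
  double x, y, phi, s;
  // motion params
  double mu, theta, turn, wallr, rear_rate, rear_dur, cbias, L;
  // social params (ignored when !social)
  double app_rate, dwell, fprop, bassert;
  bool social;
  int state;
  double timer;   // remaining time in a timed social state (s)
  double rear_t;  // remaining rearing time (s); 0 => not rearing
  double refr;    // post-encounter refractory time (s)
};

static void unpack_motion(const NumericVector& v, Mouse& m) {
  m.mu = v[0]; m.theta = v[1]; m.turn = v[2]; m.wallr = v[3];
  m.rear_rate = v[4]; m.rear_dur = v[5]; m.cbias = v[6]; m.L = v[7];
}

static void unpack_social(const NumericVector& v, Mouse& m) {
  m.app_rate = v[0]; m.dwell = v[1]; m.fprop = v[2]; m.bassert = v[3];
}

static inline void steer(Mouse& m, double desired, double gain, double dt) {
  double g = gain * dt;
  if (g > 1.0) g = 1.0;
  m.phi = wrap_pi(m.phi + wrap_pi(desired - m.phi) * g);
}

// One frame of the social automaton for mouse m against partner snapshot p.
static void social_step(Mouse& m, const Mouse& p, double dt) {
  double dx = p.x - m.x, dy = p.y - m.y;
  double d = std::sqrt(dx * dx + dy * dy);
  double pairL = 0.5 * (m.L + p.L);
  if (m.refr > 0.0) m.refr -= dt;
  switch (m.state) {
  case ROAM:
    if (m.refr <= 0.0 && unif_rand() < m.app_rate / 60.0 * dt) {
      m.state = APPROACH; m.timer = 10.0;
    } else if (m.refr <= 0.0 && d < 1.6 * pairL) {
      // the partner is upon us: the same social drive that initiates
      // approaches governs accepting the encounter; otherwise avoid it
      double accept = 10.0 * m.app_rate / 60.0;  // 1/s
      if (unif_rand() < accept * dt) {
        m.state = CONTACT; m.timer = m.dwell * exp_rand();
      } else if (unif_rand() < 0.8 * dt) {
        m.state = AVOID; m.timer = 1.0;
      }
    } else if (m.refr <= 0.0 && m.fprop > 0.0 && p.s > 5.0 &&
               d > pairL && d < 5.0 * pairL &&
               unif_rand() < m.fprop * (1.5 / 60.0) * dt) {
      m.state = FOLLOW; m.timer = 3.0 * exp_rand();
    }
    break;
  case APPROACH:
    m.timer -= dt;
    if (d < pairL) {  // close enough: the contact servo takes over
      m.state = CONTACT; m.timer = m.dwell * exp_rand();
    } else if (m.timer <= 0.0) {
      m.state = ROAM; m.refr = 2.0;
    }
    break;
  case CONTACT:
    m.timer -= dt;
    if (d > 3.0 * pairL) {  // partner left
      m.state = ROAM; m.refr = 4.0;
    } else if (m.timer <= 0.0) {
      double r = unif_rand();
      m.refr = 4.0;
      if (r < m.fprop && p.s > 4.0) {
        m.state = FOLLOW; m.timer = 3.0 * exp_rand();
      } else if (r < m.fprop + 0.5) {
        m.state = BREAK; m.timer = 1.0;
      } else {
        m.state = ROAM;
      }
    }
    break;
  case BREAK:
    m.timer -= dt;
    if (m.timer <= 0.0) { m.state = ROAM; m.refr = 2.0; }
    break;
  case FOLLOW:
    m.timer -= dt;
    if (p.s < 3.0) m.timer -= 2.0 * dt;  // give up faster on a slow leader
    if (m.timer <= 0.0 || d > 6.0 * pairL) { m.state = ROAM; m.refr = 2.0; }
    break;
  case AVOID:
    m.timer -= dt;
    if (m.timer <= 0.0 || d > 3.0 * pairL) { m.state = ROAM; m.refr = 2.0; }
    break;
  }
}

// One frame of motion for mouse m; p is the partner snapshot (may be null).
static void motion_step(Mouse& m, const Mouse* p, double side, double dt) {
  double dx = 0, dy = 0, d = 0, pairL = m.L;
  if (p) {
    dx = p->x - m.x; dy = p->y - m.y;
    d = std::sqrt(dx * dx + dy * dy);
    pairL = 0.5 * (m.L + p->L);
  }

  // rearing episodes: only initiated while roaming
  if (m.rear_t > 0.0) {
    m.rear_t -= dt;
  } else if (m.state == ROAM && unif_rand() < m.rear_rate / 60.0 * dt) {
    m.rear_t = m.rear_dur * exp_rand();
  }

  // speed target by behavioral state; roaming compensates the time lost to
  // rearing pauses so the session-mean speed tracks mean_speed
  double rear_frac = std::min(0.5, m.rear_rate * m.rear_dur / 60.0);
  double starget = m.mu / (1.0 - rear_frac);
  double noise_scale = 1.0;
  double d_hold = 0.7 * pairL;  // center distance held during a contact
  // directed social states move at engagement speeds that do not scale
  // with the roaming mean: exploratory suppression spares social motor
  // output (its counts are governed by the social parameters instead)
  switch (m.state) {
  case APPROACH:
    starget = std::max(8.0, (p ? p->s : 0.0) + 3.0);
    noise_scale = 0.3;
    break;
  case CONTACT: {
    double gap = d - d_hold;
    starget = std::min(std::max(2.0 * gap, 0.0), 6.0);
    noise_scale = 0.2;
    break;
  }
  case BREAK:
    starget = 6.0 + 4.0 * m.bassert;
    noise_scale = 0.3;
    break;
  case FOLLOW:
    noise_scale = 0.3;
    break;  // set below with the slot gap
  default: break;
  }
  if (m.state == AVOID) { starget = m.mu * 1.2; noise_scale = 0.3; }
  if (m.rear_t > 0.0) { starget = std::min(0.3, m.mu); noise_scale = 0.2; }

  // heading control
  double ang_to_partner = p ? std::atan2(dy, dx) : 0.0;
  switch (m.state) {
  case APPROACH:
    steer(m, ang_to_partner, 10.0, dt);
    m.phi = wrap_pi(m.phi + 0.2 * m.turn * std::sqrt(dt) * norm_rand());
    break;
  case CONTACT:
    steer(m, ang_to_partner, 4.0, dt);
    m.phi = wrap_pi(m.phi + 0.3 * m.turn * std::sqrt(dt) * norm_rand());
    break;
  case BREAK:
    steer(m, wrap_pi(ang_to_partner + M_PI), 10.0, dt);
    break;
  case AVOID:
    steer(m, wrap_pi(ang_to_partner + M_PI), 6.0, dt);
    m.phi = wrap_pi(m.phi + 0.3 * m.turn * std::sqrt(dt) * norm_rand());
    break;
  case FOLLOW: {
    // aim at a slot 1.5 body lengths behind the leader, matching its pace
    double sx = p->x - 1.5 * pairL * std::cos(p->phi);
    double sy = p->y - 1.5 * pairL * std::sin(p->phi);
    double gx = sx - m.x, gy = sy - m.y;
    double gap = std::sqrt(gx * gx + gy * gy);
    steer(m, gap > 0.3 ? std::atan2(gy, gx) : p->phi, 8.0, dt);
    starget = std::max(p->s + 2.0 * (gap - 0.3), 0.0);
    if (starget > 30.0) starget = 30.0;
    m.phi = wrap_pi(m.phi + 0.15 * m.turn * std::sqrt(dt) * norm_rand());
    break;
  }
  default:  // ROAM
    m.phi = wrap_pi(m.phi + m.turn * std::sqrt(dt) * norm_rand());
    if (p && m.social && d < 5.0 * pairL) {
      // proximity bias: social drive attracts toward the partner, with a
      // fixed repulsion baseline; the two balance at 5 approaches/min
      double net = 3.0 * (0.1 * m.app_rate - 0.5);
      if (net > 0.0) steer(m, ang_to_partner, net, dt);
      else if (net < 0.0) steer(m, wrap_pi(ang_to_partner + M_PI), -net, dt);
    }
    {
      // wall steering toward the interior
      double dwall = std::min(std::min(m.x, side - m.x),
                              std::min(m.y, side - m.y));
      double ang_c = std::atan2(side / 2.0 - m.y, side / 2.0 - m.x);
      if (dwall < m.wallr) {
        double w = 1.0 - dwall / m.wallr;
        steer(m, ang_c, 6.0 * w, dt);
      }
      if (m.cbias != 0.0) {
        double des = m.cbias > 0.0 ? ang_c : wrap_pi(ang_c + M_PI);
        steer(m, des, std::fabs(m.cbias), dt);
      }
    }
    break;
  }

  // Ornstein-Uhlenbeck speed update, reflected at zero. The stationary sd
  // is 0.6 * mean_speed; directed states use reduced noise.
  double sigma = 0.6 * m.mu * std::sqrt(2.0 * m.theta) * noise_scale;
  m.s += m.theta * (starget - m.s) * dt + sigma * std::sqrt(dt) * norm_rand();
  if (m.s < 0.0) m.s = -m.s;

  // position update with reflecting walls (0.5 cm margin)
  m.x += m.s * std::cos(m.phi) * dt;
  m.y += m.s * std::sin(m.phi) * dt;
  double lo = 0.5, hi = side - 0.5;
  if (m.x < lo) { m.x = 2 * lo - m.x; m.phi = wrap_pi(M_PI - m.phi); }
  if (m.x > hi) { m.x = 2 * hi - m.x; m.phi = wrap_pi(M_PI - m.phi); }
  if (m.y < lo) { m.y = 2 * lo - m.y; m.phi = wrap_pi(-m.phi); }
  if (m.y > hi) { m.y = 2 * hi - m.y; m.phi = wrap_pi(-m.phi); }
}

static void record(NumericMatrix& out, int i, const Mouse& m, double dt,
                   double noise_sd) {
  double L_eff = m.L * (m.rear_t > 0.0 ? 0.45 : 1.0);
  double axis = m.phi + 0.05 * norm_rand();
  double cx = m.x + noise_sd * norm_rand();
  double cy = m.y + noise_sd * norm_rand();
  out(i, 0) = i * dt;
  out(i, 1) = cx;
  out(i, 2) = cy;
  out(i, 3) = cx + 0.5 * L_eff * std::cos(axis);
  out(i, 4) = cy + 0.5 * L_eff * std::sin(axis);
  out(i, 5) = cx - 0.5 * L_eff * std::cos(axis);
  out(i, 6) = cy - 0.5 * L_eff * std::sin(axis);
  out(i, 7) = (m.rear_t > 0.0 ? 0.85 : 0.05) + 0.1 * unif_rand();
}

// [[Rcpp::export]]
List sim_session_cpp(NumericVector motion_f, NumericVector motion_p,
                     NumericVector social_f, NumericVector social_p,
                     int n_frames, double dt, double side, bool dyad,
                     double noise_sd) {
  Mouse f, p;
  unpack_motion(motion_f, f);
  f.social = dyad;
  f.state = ROAM; f.timer = 0.0; f.rear_t = 0.0; f.refr = 0.0;
  if (dyad) {
    unpack_motion(motion_p, p);
    unpack_social(social_f, f);
    unpack_social(social_p, p);
    p.social = true; p.state = ROAM; p.timer = 0.0; p.rear_t = 0.0;
    p.refr = 0.0;
  }

  // initial conditions: uniform in the central 60% of the arena
  f.x = side * (0.2 + 0.6 * unif_rand());
  f.y = side * (0.2 + 0.6 * unif_rand());
  f.phi = wrap_pi(2.0 * M_PI * unif_rand());
  f.s = f.mu;
  if (dyad) {
    p.x = side * (0.2 + 0.6 * unif_rand());
    p.y = side * (0.2 + 0.6 * unif_rand());
    p.phi = wrap_pi(2.0 * M_PI * unif_rand());
    p.s = p.mu;
  }

  NumericMatrix out_f(n_frames, 8), out_p(dyad ? n_frames : 0, 8);
  IntegerVector st_f(n_frames), st_p(dyad ? n_frames : 0);
  record(out_f, 0, f, dt, noise_sd);
  st_f[0] = f.state;
  if (dyad) { record(out_p, 0, p, dt, noise_sd); st_p[0] = p.state; }

  for (int i = 1; i < n_frames; ++i) {
    if (dyad) {
      Mouse f_prev = f, p_prev = p;
      social_step(f, p_prev, dt);
      social_step(p, f_prev, dt);
      motion_step(f, &p_prev, side, dt);
      motion_step(p, &f_prev, side, dt);
    } else {
      motion_step(f, nullptr, side, dt);
    }
    record(out_f, i, f, dt, noise_sd);
    st_f[i] = f.state;
    if (dyad) { record(out_p, i, p, dt, noise_sd); st_p[i] = p.state; }
  }

  colnames(out_f) = CharacterVector::create("t", "cx", "cy", "nx", "ny",
                                            "tx", "ty", "posture");
  if (dyad)
    colnames(out_p) = CharacterVector::create("t", "cx", "cy", "nx", "ny",
                                              "tx", "ty", "posture");
  return List::create(_["focal"] = out_f, _["partner"] = out_p,
                      _["state_focal"] = st_f, _["state_partner"] = st_p);
}
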