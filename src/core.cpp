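// Compiled core: fixed-step integration of the excitatory-inhibitory rate
// field on a periodic grid, the Benettin renormalized-perturbation loop for
// the maximal Lyapunov exponent, and reproducible Ornstein-Uhlenbeck input
// noise streams.
//
// Spatial coupling uses the separable form of the wrapped Gaussian on the
// torus: the 2D spectral convolution equals G * F * G with G the symmetric
// circulant matrix built from the 1D Fourier coefficients, which is exact
// (same operator as FFT multiply) and much faster via BLAS at these sizes.
#include <RcppArmadillo.h>
using namespace arma;

static const double OVERFLOW_GUARD = 1e6;

// ---------------------------------------------------------------------------
// Counter-seeded RNG streams (xoshiro256++ seeded through splitmix64) so that
// every noise path is a pure function of (seed, population, unit index) and
// realizations are bitwise reproducible regardless of how units are visited.
// ---------------------------------------------------------------------------
static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t stream_key(uint64_t seed, uint64_t pop, uint64_t unit) {
  uint64_t x = seed;
  uint64_t a = splitmix64(x);
  x ^= pop * 0xD1B54A32D192ED03ULL;
  uint64_t b = splitmix64(x);
  x ^= (unit + 1) * 0x9E3779B97f4A7C15ULL;
  uint64_t c = splitmix64(x);
  return a ^ (b << 1) ^ (c << 2) ^ splitmix64(x);
}

struct RngStream {
  uint64_t s[4];
  double spare;
  bool has_spare;

  void seed(uint64_t key) {
    uint64_t x = key;
    for (int i = 0; i < 4; i++) s[i] = splitmix64(x);
    has_spare = false;
    spare = 0.0;
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {  // standard normal, Box-Muller
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925287 * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

// ---------------------------------------------------------------------------
// Ornstein-Uhlenbeck input noise: one common stream per population plus one
// private stream per unit. Exact discretization over dt: the stationary law
// (variance 1/(2 tau_n), or 1 when normalized to unit variance) is preserved.
// ---------------------------------------------------------------------------
struct NoiseField {
  bool active = false;
  double sigma_n = 0.0, corr = 0.0, tau_n = 5.0;
  bool normalize = true;
  double rho = 0.0, step_sd = 0.0, sd0 = 0.0, sqc = 0.0, sq1c = 0.0;
  double eta_c_e = 0.0, eta_c_i = 0.0;
  mat eta_e, eta_i;
  std::vector<RngStream> rng_e, rng_i;
  RngStream rng_ce, rng_ci;

  void init(double sigma_n_, double corr_, double tau_n_, bool normalize_,
            uint64_t seed, uword nr, uword nc, double dt) {
    active = true;
    sigma_n = sigma_n_;
    corr = corr_;
    tau_n = tau_n_;
    normalize = normalize_;
    rho = std::exp(-dt / tau_n);
    double v = normalize ? 1.0 : 1.0 / (2.0 * tau_n);
    sd0 = std::sqrt(v);
    step_sd = std::sqrt((1.0 - rho * rho) * v);
    sqc = std::sqrt(corr);
    sq1c = std::sqrt(1.0 - corr);
    uword n = nr * nc;
    rng_e.resize(n);
    rng_i.resize(n);
    for (uword k = 0; k < n; k++) {
      rng_e[k].seed(stream_key(seed, 1, k + 1));
      rng_i[k].seed(stream_key(seed, 2, k + 1));
    }
    rng_ce.seed(stream_key(seed, 1, 0));
    rng_ci.seed(stream_key(seed, 2, 0));
    eta_e.set_size(nr, nc);
    eta_i.set_size(nr, nc);
    for (uword k = 0; k < n; k++) {
      eta_e(k) = sd0 * rng_e[k].norm();
      eta_i(k) = sd0 * rng_i[k].norm();
    }
    eta_c_e = sd0 * rng_ce.norm();
    eta_c_i = sd0 * rng_ci.norm();
  }

  inline void step() {
    uword n = eta_e.n_elem;
    for (uword k = 0; k < n; k++) {
      eta_e(k) = rho * eta_e(k) + step_sd * rng_e[k].norm();
      eta_i(k) = rho * eta_i(k) + step_sd * rng_i[k].norm();
    }
    eta_c_e = rho * eta_c_e + step_sd * rng_ce.norm();
    eta_c_i = rho * eta_c_i + step_sd * rng_ci.norm();
  }

  // total noisy input deviation from the static drive
  inline mat input_e() const { return sigma_n * (sq1c * eta_e + sqc * eta_c_e); }
  inline mat input_i() const { return sigma_n * (sq1c * eta_i + sqc * eta_c_i); }
};

// ---------------------------------------------------------------------------
// Model right-hand side
// ---------------------------------------------------------------------------
struct Model {
  double Wee, Wei, Wie, Wii, tau_e, tau_i, mu_e, mu_i, dt;
  mat Ge, Gi;
  bool two_d;

  inline mat conv(const mat &F, const mat &G) const {
    if (two_d) return G * F * G;
    return G * F;
  }
  static inline mat phi(const mat &u) {
    mat up = arma::clamp(u, 0.0, datum::inf);
    return up % up;
  }
  void drift(const mat &re, const mat &ri, const mat *ne, const mat *ni,
             mat &de, mat &di) const {
    mat ce = conv(re, Ge), ci = conv(ri, Gi);
    mat ue = Wee * ce + Wei * ci + mu_e;
    mat ui = Wie * ce + Wii * ci + mu_i;
    if (ne) ue += *ne;
    if (ni) ui += *ni;
    de = (-re + phi(ue)) / tau_e;
    di = (-ri + phi(ui)) / tau_i;
  }
  // classical RK4; any OU input (ne/ni) is held constant over the step and
  // updated by its exact discretization at step boundaries
  void rk4_step(mat &re, mat &ri, const mat *ne = nullptr,
                const mat *ni = nullptr) const {
    mat k1e, k1i, k2e, k2i, k3e, k3i, k4e, k4i;
    drift(re, ri, ne, ni, k1e, k1i);
    {
      mat ae = re + 0.5 * dt * k1e, ai = ri + 0.5 * dt * k1i;
      drift(ae, ai, ne, ni, k2e, k2i);
    }
    {
      mat ae = re + 0.5 * dt * k2e, ai = ri + 0.5 * dt * k2i;
      drift(ae, ai, ne, ni, k3e, k3i);
    }
    {
      mat ae = re + dt * k3e, ai = ri + dt * k3i;
      drift(ae, ai, ne, ni, k4e, k4i);
    }
    re += (dt / 6.0) * (k1e + 2.0 * k2e + 2.0 * k3e + k4e);
    ri += (dt / 6.0) * (k1i + 2.0 * k2i + 2.0 * k3i + k4i);
  }
};

static void check_finite(const mat &re, const mat &ri, int step) {
  if (!re.is_finite() || !ri.is_finite() ||
      re.max() > OVERFLOW_GUARD || ri.max() > OVERFLOW_GUARD) {
    Rcpp::stop("rate overflow (>1e6) or non-finite value at integration step %d",
               step);
  }
}

static Model make_model(const Rcpp::List &pars, const mat &Ge, const mat &Gi,
                        bool two_d) {
  Model m;
  m.Wee = pars["W_ee"];
  m.Wei = pars["W_ei"];
  m.Wie = pars["W_ie"];
  m.Wii = pars["W_ii"];
  m.tau_e = pars["tau_e"];
  m.tau_i = pars["tau_i"];
  m.mu_e = pars["mu_e"];
  m.mu_i = pars["mu_i"];
  m.dt = pars["dt"];
  m.Ge = Ge;
  m.Gi = Gi;
  m.two_d = two_d;
  return m;
}

static bool noise_from_list(const Rcpp::List &noise, NoiseField &nf,
                            uint64_t seed, uword nr, uword nc, double dt) {
  if (noise.size() == 0) return false;
  double sn = noise["sigma_n"];
  if (sn <= 0.0) return false;
  nf.init(sn, Rcpp::as<double>(noise["c"]), Rcpp::as<double>(noise["tau_n"]),
          Rcpp::as<bool>(noise["normalize"]), seed, nr, nc, dt);
  return true;
}

// [[Rcpp::export]]
Rcpp::List cpp_simulate(const arma::mat &re0, const arma::mat &ri0,
                        const Rcpp::List &pars, const arma::mat &Ge,
                        const arma::mat &Gi, bool two_d, int n_steps,
                        int record_stride, bool record_ri,
                        const Rcpp::IntegerVector &record_units,
                        const Rcpp::List &noise, double noise_seed,
                        double t0) {
  Model m = make_model(pars, Ge, Gi, two_d);
  mat re = re0, ri = ri0;
  NoiseField nf;
  bool noisy = noise_from_list(noise, nf, (uint64_t)noise_seed, re.n_rows,
                               re.n_cols, m.dt);
  uword n_units = re.n_elem;

  int n_rec = (record_stride > 0) ? n_steps / record_stride + 1 : 0;
  mat rec_re, rec_ri;
  vec rec_t;
  if (n_rec > 0) {
    rec_re.set_size(n_rec, n_units);
    if (record_ri) rec_ri.set_size(n_rec, n_units);
    rec_t.set_size(n_rec);
  }
  int n_uts = record_units.size();
  mat rec_u;
  vec rec_ut;
  if (n_uts > 0) {
    rec_u.set_size(n_steps + 1, n_uts);
    rec_ut.set_size(n_steps + 1);
  }

  int irec = 0;
  for (int step = 0; step <= n_steps; step++) {
    if (n_rec > 0 && record_stride > 0 && step % record_stride == 0 &&
        irec < n_rec) {
      rec_re.row(irec) = vectorise(re).t();
      if (record_ri) rec_ri.row(irec) = vectorise(ri).t();
      rec_t(irec) = t0 + step * m.dt;
      irec++;
    }
    if (n_uts > 0) {
      for (int j = 0; j < n_uts; j++)
        rec_u(step, j) = re(record_units[j] - 1);
      rec_ut(step) = t0 + step * m.dt;
    }
    if (step == n_steps) break;
    if (noisy) {
      mat ne = nf.input_e(), ni = nf.input_i();
      m.rk4_step(re, ri, &ne, &ni);
      nf.step();
    } else {
      m.rk4_step(re, ri);
    }
    if (step % 100 == 0 || step == n_steps - 1) check_finite(re, ri, step + 1);
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("final_re") = re, Rcpp::Named("final_ri") = ri,
      Rcpp::Named("n_steps") = n_steps);
  if (n_rec > 0) {
    out["t"] = rec_t.head(irec);
    out["re"] = rec_re.rows(0, irec - 1);
    if (record_ri) out["ri"] = rec_ri.rows(0, irec - 1);
  }
  if (n_uts > 0) {
    out["unit_t"] = rec_ut;
    out["unit_re"] = rec_u;
  }
  return out;
}

// Benettin renormalized-perturbation estimate of the maximal Lyapunov
// exponent. Reference and perturbed trajectories advance in lockstep and,
// when noise is active, share the identical frozen realization.
// [[Rcpp::export]]
Rcpp::List cpp_mle(const arma::mat &re0, const arma::mat &ri0,
                   const Rcpp::List &pars, const arma::mat &Ge,
                   const arma::mat &Gi, bool two_d, int n_transient_steps,
                   int n_renorm, int steps_per_renorm, double dM,
                   const Rcpp::List &noise, double noise_seed,
                   double direction_seed) {
  Model m = make_model(pars, Ge, Gi, two_d);
  mat re = re0, ri = ri0;
  NoiseField nf;
  bool noisy = noise_from_list(noise, nf, (uint64_t)noise_seed, re.n_rows,
                               re.n_cols, m.dt);

  // reference transient onto the attractor
  for (int step = 0; step < n_transient_steps; step++) {
    if (noisy) {
      mat ne = nf.input_e(), ni = nf.input_i();
      m.rk4_step(re, ri, &ne, &ni);
      nf.step();
    } else {
      m.rk4_step(re, ri);
    }
    if (step % 200 == 0) check_finite(re, ri, step + 1);
  }

  // random initial perturbation direction of magnitude dM
  uword n = re.n_elem;
  RngStream rs;
  rs.seed(stream_key((uint64_t)direction_seed, 7, 0));
  vec dz(2 * n);
  for (uword k = 0; k < 2 * n; k++) dz(k) = rs.norm();
  dz *= dM / norm(dz, 2);
  mat rpe = re, rpi = ri;
  rpe += reshape(dz.head(n), re.n_rows, re.n_cols);
  rpi += reshape(dz.tail(n), ri.n_rows, ri.n_cols);

  vec log_terms(n_renorm);
  for (int i = 0; i < n_renorm; i++) {
    for (int s = 0; s < steps_per_renorm; s++) {
      if (noisy) {
        mat ne = nf.input_e(), ni = nf.input_i();
        m.rk4_step(re, ri, &ne, &ni);
        m.rk4_step(rpe, rpi, &ne, &ni);
        nf.step();
      } else {
        m.rk4_step(re, ri);
        m.rk4_step(rpe, rpi);
      }
    }
    check_finite(re, ri, (i + 1) * steps_per_renorm);
    mat De = rpe - re, Di = rpi - ri;
    double d = std::sqrt(accu(De % De) + accu(Di % Di));
    if (d <= 0.0 || !std::isfinite(d))
      Rcpp::stop(
          "trajectory separation underflow/overflow at renormalization %d; "
          "adjust dM",
          i + 1);
    log_terms(i) = std::log(d / dM);
    double scale = dM / d;
    rpe = re + scale * De;
    rpi = ri + scale * Di;
  }

  return Rcpp::List::create(
      Rcpp::Named("log_terms") = log_terms, Rcpp::Named("final_re") = re,
      Rcpp::Named("final_ri") = ri);
}

// Two-unit (no spatial coupling) reduction, RK4.
// [[Rcpp::export]]
Rcpp::List cpp_two_unit(double re0, double ri0, const Rcpp::List &pars,
                        double dt, int n_steps, int record_stride) {
  double Wee = pars["W_ee"], Wei = pars["W_ei"], Wie = pars["W_ie"],
         Wii = pars["W_ii"], tau_e = pars["tau_e"], tau_i = pars["tau_i"],
         mu_e = pars["mu_e"], mu_i = pars["mu_i"];
  auto phi = [](double u) { return u > 0 ? u * u : 0.0; };
  auto fe = [&](double re, double ri) {
    return (-re + phi(Wee * re + Wei * ri + mu_e)) / tau_e;
  };
  auto fi = [&](double re, double ri) {
    return (-ri + phi(Wie * re + Wii * ri + mu_i)) / tau_i;
  };
  double re = re0, ri = ri0;
  int n_rec = (record_stride > 0) ? n_steps / record_stride + 1 : 0;
  vec rec_re(n_rec > 0 ? n_rec : 1), rec_ri(n_rec > 0 ? n_rec : 1),
      rec_t(n_rec > 0 ? n_rec : 1);
  int irec = 0;
  for (int step = 0; step <= n_steps; step++) {
    if (n_rec > 0 && step % record_stride == 0 && irec < n_rec) {
      rec_re(irec) = re;
      rec_ri(irec) = ri;
      rec_t(irec) = step * dt;
      irec++;
    }
    if (step == n_steps) break;
    double k1e = fe(re, ri), k1i = fi(re, ri);
    double k2e = fe(re + 0.5 * dt * k1e, ri + 0.5 * dt * k1i),
           k2i = fi(re + 0.5 * dt * k1e, ri + 0.5 * dt * k1i);
    double k3e = fe(re + 0.5 * dt * k2e, ri + 0.5 * dt * k2i),
           k3i = fi(re + 0.5 * dt * k2e, ri + 0.5 * dt * k2i);
    double k4e = fe(re + dt * k3e, ri + dt * k3i),
           k4i = fi(re + dt * k3e, ri + dt * k3i);
    re += (dt / 6.0) * (k1e + 2.0 * k2e + 2.0 * k3e + k4e);
    ri += (dt / 6.0) * (k1i + 2.0 * k2i + 2.0 * k3i + k4i);
    if (!std::isfinite(re) || !std::isfinite(ri) || re > OVERFLOW_GUARD ||
        ri > OVERFLOW_GUARD)
      Rcpp::stop("rate overflow or non-finite value at integration step %d",
                 step + 1);
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("final_re") = re,
                                      Rcpp::Named("final_ri") = ri);
  if (n_rec > 0) {
    out["t"] = rec_t.head(irec);
    out["re"] = rec_re.head(irec);
    out["ri"] = rec_ri.head(irec);
  }
  return out;
}

// Expose the OU streams used by the simulator: returns the paths (rows =
// times 0..n_steps) for the requested units of one population; unit index 0
// denotes the population's common stream.
// [[Rcpp::export]]
arma::mat cpp_noise_paths(double seed, int population,
                          const Rcpp::IntegerVector &units, int n_steps,
                          double dt, double tau_n, bool normalize) {
  double rho = std::exp(-dt / tau_n);
  double v = normalize ? 1.0 : 1.0 / (2.0 * tau_n);
  double sd0 = std::sqrt(v);
  double step_sd = std::sqrt((1.0 - rho * rho) * v);
  int k = units.size();
  mat out(n_steps + 1, k);
  for (int j = 0; j < k; j++) {
    RngStream rs;
    rs.seed(stream_key((uint64_t)seed, (uint64_t)population,
                       (uint64_t)units[j]));
    double eta = sd0 * rs.norm();
    out(0, j) = eta;
    for (int s = 1; s <= n_steps; s++) {
      eta = rho * eta + step_sd * rs.norm();
      out(s, j) = eta;
    }
  }
  return out;
}
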