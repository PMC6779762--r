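#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact stochastic simulation of a reaction network whose propensities are
// constant between events except for exponentially decaying input hazards.
// Time dependence is handled by Ogata thinning: the total propensity at the
// proposal origin bounds the true total over the waiting interval because the
// only time-varying hazards are non-increasing and every other propensity is
// frozen until the next state change.  Extrinsic-noise update times are hard
// barriers -- the clock never jumps across one -- so a lognormal redraw
// (which may *raise* a propensity) can never invalidate the bound.
//
// Propensity type codes (keep in sync with R/reaction_models.R):
//   0 CONST       coef
//   1 LINEAR      coef * x[s1]
//   2 BILINEAR    coef * x[s1] * x[s2]
//   3 HILL_PROD   coef * (x[s1]*x[s2])^n / ((x[s1]*x[s2])^n + K^n)
//   4 HILL_GATE   coef * x[s2] * x[s1]^n / (x[s1]^n + K^n)
//   5 INPUT_PROD  coef * exp(-t/T)
//   6 INPUT_DEG   coef * exp(-t/T) * 1{x[s1] > 0}
// aux columns: (n, K) for Hill types, (T, unused) for input types.

namespace {

struct Engine {
  int nr, ns;
  std::vector<int> type, s1, s2;
  std::vector<double> coef, auxn, Kn, invT;
  std::vector<std::vector<std::pair<int, int> > > delta;  // reaction -> (species, change)
  std::vector<std::vector<int> > readers;  // species -> const reactions reading it
  std::vector<char> gate_reader;           // species read by a type-6 gate?
  std::vector<double> x, prop;             // state, cached const propensities
  double sum_const;
  std::vector<int> tdep;                   // indices of types 5/6
  // cache of the time-dependent total (valid at time tp_t unless dirty)
  double tp_t, tp_val;
  bool tp_dirty, tp_dead;

  Engine(const IntegerMatrix& S, const IntegerVector& ty,
         const NumericVector& cf, const IntegerMatrix& si,
         const NumericMatrix& au, const IntegerVector& init)
      : nr(S.nrow()), ns(S.ncol()), type(ty.begin(), ty.end()),
        s1(nr), s2(nr), coef(cf.begin(), cf.end()), auxn(nr), Kn(nr, 0.0),
        invT(nr, 0.0), delta(nr), readers(ns), gate_reader(ns, 0),
        x(init.begin(), init.end()), prop(nr, 0.0), sum_const(0.0),
        tp_t(-1.0), tp_val(0.0), tp_dirty(true), tp_dead(false) {
    for (int r = 0; r < nr; ++r) {
      s1[r] = si(r, 0);
      s2[r] = si(r, 1);
      auxn[r] = au(r, 0);
      if (type[r] == 3 || type[r] == 4) Kn[r] = std::pow(au(r, 1), au(r, 0));
      if (type[r] == 5 || type[r] == 6) {
        invT[r] = 1.0 / au(r, 0);
        tdep.push_back(r);
        if (type[r] == 6) gate_reader[s1[r]] = 1;
      } else {
        if (s1[r] >= 0) readers[s1[r]].push_back(r);
        if (s2[r] >= 0) readers[s2[r]].push_back(r);
      }
      for (int s = 0; s < ns; ++s)
        if (S(r, s) != 0) delta[r].push_back(std::make_pair(s, S(r, s)));
    }
    refresh_const();
  }

  double eval(int r, double t) const {
    switch (type[r]) {
      case 0: return coef[r];
      case 1: return coef[r] * x[s1[r]];
      case 2: return coef[r] * x[s1[r]] * x[s2[r]];
      case 3: {
        double v = x[s1[r]] * x[s2[r]];
        if (v <= 0.0) return 0.0;
        double vn = std::pow(v, auxn[r]);
        return coef[r] * vn / (vn + Kn[r]);
      }
      case 4: {
        double tf = x[s1[r]], g = x[s2[r]];
        if (tf <= 0.0 || g <= 0.0) return 0.0;
        double vn = std::pow(tf, auxn[r]);
        return coef[r] * g * vn / (vn + Kn[r]);
      }
      case 5: return coef[r] * std::exp(-t * invT[r]);
      case 6: return x[s1[r]] > 0.0
                  ? coef[r] * std::exp(-t * invT[r]) : 0.0;
    }
    return 0.0;  // not reached
  }

  void refresh_const() {
    sum_const = 0.0;
    for (int r = 0; r < nr; ++r) {
      if (type[r] >= 5) continue;
      prop[r] = eval(r, 0.0);
      if (prop[r] < 0.0) stop("negative propensity in reaction %d", r + 1);
      sum_const += prop[r];
    }
  }

  // total of the time-dependent hazards; monotone non-increasing along a
  // trajectory, so once it underflows it can be dropped for good
  double tdep_total(double t) {
    if (tp_dead) return 0.0;
    if (!tp_dirty && t == tp_t) return tp_val;
    double s = 0.0;
    for (size_t k = 0; k < tdep.size(); ++k) s += eval(tdep[k], t);
    tp_t = t;
    tp_val = s;
    tp_dirty = false;
    if (s < 1e-14) { tp_dead = true; tp_val = 0.0; }
    return tp_val;
  }

  void fire(int r) {
    const std::vector<std::pair<int, int> >& d = delta[r];
    for (size_t i = 0; i < d.size(); ++i) {
      int s = d[i].first;
      x[s] += d[i].second;
      if (x[s] < 0.0) stop("species count went negative (reaction %d)", r + 1);
      if (gate_reader[s]) tp_dirty = true;
      const std::vector<int>& dep = readers[s];
      for (size_t k = 0; k < dep.size(); ++k) {
        int q = dep[k];
        double old = prop[q];
        prop[q] = eval(q, 0.0);
        if (prop[q] < 0.0) stop("negative propensity in reaction %d", q + 1);
        sum_const += prop[q] - old;
      }
    }
  }

  int select(double t, double total) {
    double u = unif_rand() * total, acc = 0.0;
    int last = -1;
    for (int r = 0; r < nr; ++r) {
      double p = (type[r] >= 5) ? eval(r, t) : prop[r];
      if (p <= 0.0) continue;
      acc += p;
      last = r;
      if (u <= acc) return r;
    }
    return last;  // floating-point slack: fall back to last active reaction
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerMatrix ssa_run_cpp(IntegerMatrix stoich, IntegerVector prop_type,
                          NumericVector coef, IntegerMatrix sidx,
                          NumericMatrix aux, IntegerVector init,
                          NumericVector sample_times, double t_end,
                          int noisy_rxn, double eps_noise, double p_ext,
                          double noisy_nominal) {
  Engine eng(stoich, prop_type, coef, sidx, aux, init);
  const int nsamp = sample_times.size();
  IntegerMatrix out(nsamp, eng.ns);
  int si = 0;
  long long nev = 0;

  bool noisy = noisy_rxn >= 0;
  double next_update = t_end;
  if (noisy) {
    double old = eng.prop[noisy_rxn];
    eng.coef[noisy_rxn] = eps_noise > 0.0
        ? noisy_nominal * std::exp(eps_noise * norm_rand())
        : noisy_nominal;
    eng.prop[noisy_rxn] = eng.eval(noisy_rxn, 0.0);
    eng.sum_const += eng.prop[noisy_rxn] - old;
    if (eps_noise > 0.0 && p_ext < t_end) next_update = p_ext;
  }

  double t = 0.0;
  while (t < t_end) {
    double bound = eng.sum_const + eng.tdep_total(t);
    double t1 = bound > 0.0 ? t + exp_rand() / bound : next_update;
    if (t1 >= next_update) {  // barrier: clamp, redraw noise, re-bound
      while (si < nsamp && sample_times[si] < next_update) {
        for (int s = 0; s < eng.ns; ++s)
          out(si, s) = static_cast<int>(eng.x[s]);
        ++si;
      }
      t = next_update;
      if (t >= t_end) break;
      double old = eng.prop[noisy_rxn];
      eng.coef[noisy_rxn] = noisy_nominal * std::exp(eps_noise * norm_rand());
      eng.prop[noisy_rxn] = eng.eval(noisy_rxn, 0.0);
      eng.sum_const += eng.prop[noisy_rxn] - old;
      next_update += p_ext;
      if (next_update > t_end) next_update = t_end;
      continue;
    }
    while (si < nsamp && sample_times[si] < t1) {
      for (int s = 0; s < eng.ns; ++s)
        out(si, s) = static_cast<int>(eng.x[s]);
      ++si;
    }
    double total = eng.sum_const + eng.tdep_total(t1);
    t = t1;
    if (total > 0.0 && unif_rand() * bound <= total) {
      eng.fire(eng.select(t1, total));
      if (++nev % 100000 == 0) {
        eng.refresh_const();          // guard against float drift
        if (nev % 10000000 == 0) Rcpp::checkUserInterrupt();
      }
    }
  }

  while (si < nsamp) {
    for (int s = 0; s < eng.ns; ++s)
      out(si, s) = static_cast<int>(eng.x[s]);
    ++si;
  }
  return out;
}
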