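#include <Rcpp.h>
#include <queue>
#include <vector>
#include <string>
using namespace Rcpp;

// Age-structured (Bellman-Harris) pure-birth simulation on an event queue.
// Each individual lives an i.i.d. Erlang(stages, mean/stages) division time,
// then is replaced by two newborns with fresh draws. Uses R's RNG so results
// are reproducible under set.seed().

static inline double draw_division(int stages, double scale) {
  // Erlang(k, scale) == chi-squared(2k) rescaled to mean k*scale
  return R::rgamma((double)stages, scale);
}

static inline double draw_initial(const std::string &phase, int stages,
                                  double scale, double mean_division,
                                  double phase_window) {
  if (phase == "uniform") return R::runif(0.0, phase_window);
  if (phase == "exponential") return R::rexp(mean_division);
  return draw_division(stages, scale); // "zero": age zero, full fresh draw
}

// [[Rcpp::export]]
NumericVector bh_fpt_cpp(IntegerVector inocula, double omega, int stages,
                         double mean_division, std::string phase,
                         double phase_window, double event_budget) {
  int n_reps = inocula.size();
  NumericVector out(n_reps);
  double scale = mean_division / stages;
  typedef std::priority_queue<double, std::vector<double>,
                              std::greater<double> > min_heap;
  for (int r = 0; r < n_reps; ++r) {
    int k = inocula[r];
    if (k >= omega) { out[r] = 0.0; continue; }
    min_heap q;
    for (int i = 0; i < k; ++i)
      q.push(draw_initial(phase, stages, scale, mean_division, phase_window));
    double n = k;
    double res = NA_REAL;
    double events = 0.0;
    while (!q.empty()) {
      double t = q.top();
      q.pop();
      n += 1.0; // one parent replaced by two offspring
      events += 1.0;
      if (n >= omega) { res = t; break; }
      if (events > event_budget) break;
      q.push(t + draw_division(stages, scale));
      q.push(t + draw_division(stages, scale));
    }
    out[r] = res;
  }
  return out;
}

// Division-event times of one replicate until the population reaches `cap`.
// [[Rcpp::export]]
NumericVector bh_events_cpp(int inoculum, double cap, int stages,
                            double mean_division, std::string phase,
                            double phase_window) {
  double scale = mean_division / stages;
  typedef std::priority_queue<double, std::vector<double>,
                              std::greater<double> > min_heap;
  min_heap q;
  for (int i = 0; i < inoculum; ++i)
    q.push(draw_initial(phase, stages, scale, mean_division, phase_window));
  std::vector<double> times;
  double n = inoculum;
  while (!q.empty() && n < cap) {
    double t = q.top();
    q.pop();
    n += 1.0;
    times.push_back(t);
    if (n >= cap) break;
    q.push(t + draw_division(stages, scale));
    q.push(t + draw_division(stages, scale));
  }
  return wrap(times);
}
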