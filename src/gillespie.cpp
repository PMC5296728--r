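#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact stochastic simulation of the birth-death process
//   0 -> mRNA at rate k_b(t),  mRNA -> 0 at rate k_d(t) * m
// with piecewise-constant rate schedules.  Waiting times are drawn as
// exponentials at the current total propensity; a draw that overshoots the
// next rate breakpoint advances the clock to the breakpoint and is re-drawn,
// which is exact by memorylessness of the exponential within each
// constant-rate window.  Uses R's RNG so set.seed() governs reproducibility.
//
// birth_breaks/death_breaks: segment start times (first must be 0), sorted.
// sample_times: sorted, within [0, t_max]; counts are recorded with the
// right-continuous convention (a sample at an event time sees the post-event
// state).
// [[Rcpp::export]]
List simulate_bd_cpp(NumericVector birth_breaks, NumericVector birth_levels,
                     NumericVector death_breaks, NumericVector death_levels,
                     int m0, double t_max, NumericVector sample_times,
                     bool keep_events) {
    const int nb = birth_breaks.size(), nd = death_breaks.size();
    const int ns = sample_times.size();
    int ib = 0, id = 0;          // current segment index in each schedule
    double t = 0.0;
    long m = m0;
    int is = 0;                  // next sample index to fill
    IntegerVector sampled(ns);
    std::vector<double> ev_t;
    std::vector<int> ev_d;

    RNGScope scope;

    while (t < t_max) {
        // advance schedule indices to the segments containing t
        while (ib + 1 < nb && birth_breaks[ib + 1] <= t) ++ib;
        while (id + 1 < nd && death_breaks[id + 1] <= t) ++id;
        const double kb = birth_levels[ib];
        const double kd = death_levels[id];
        double t_next = t_max;
        if (ib + 1 < nb && birth_breaks[ib + 1] < t_next) t_next = birth_breaks[ib + 1];
        if (id + 1 < nd && death_breaks[id + 1] < t_next) t_next = death_breaks[id + 1];

        const double a = kb + kd * (double)m;
        double t_new;
        bool event = false;
        if (a <= 0.0) {
            t_new = t_next;
        } else {
            const double tau = R::exp_rand() / a;
            if (t + tau >= t_next) {
                t_new = t_next;       // horizon hit: move to breakpoint, re-draw
            } else {
                t_new = t + tau;
                event = true;
            }
        }
        // samples strictly before the event/breakpoint see the current state
        while (is < ns && sample_times[is] < t_new) sampled[is++] = (int)m;
        if (event) {
            if (R::unif_rand() * a < kb) {
                ++m;
                if (keep_events) { ev_t.push_back(t_new); ev_d.push_back(1); }
            } else {
                --m;
                if (keep_events) { ev_t.push_back(t_new); ev_d.push_back(-1); }
            }
        }
        t = t_new;
    }
    while (is < ns) sampled[is++] = (int)m;

    return List::create(_["sampled_counts"] = sampled,
                        _["event_times"] = wrap(ev_t),
                        _["event_deltas"] = wrap(ev_d),
                        _["final_count"] = (int)m);
}
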