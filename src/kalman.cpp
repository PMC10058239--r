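#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Fast internal RNG for the particle filter (xoshiro256++ with Box-Muller
// normals). The stream is seeded explicitly from R so that results remain
// reproducible under set.seed() while avoiding the per-draw overhead of the
// R RNG inside the particle loop.
namespace {

struct FastRng {
    uint64_t s[4];
    double cached_norm;
    bool has_cached;

    explicit FastRng(uint64_t seed) : cached_norm(0.0), has_cached(false) {
        // splitmix64 expansion of the seed
        uint64_t z = seed;
        for (int i = 0; i < 4; ++i) {
            z += 0x9e3779b97f4a7c15ULL;
            uint64_t t = z;
            t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
            t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
            s[i] = t ^ (t >> 31);
        }
    }

    static inline uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }

    inline uint64_t next() {
        uint64_t result = rotl(s[0] + s[3], 23) + s[0];
        uint64_t t = s[1] << 17;
        s[2] ^= s[0];
        s[3] ^= s[1];
        s[1] ^= s[2];
        s[0] ^= s[3];
        s[2] ^= t;
        s[3] = rotl(s[3], 45);
        return result;
    }

    inline double unif() {
        // in (0, 1); never exactly 0
        return (((double)(next() >> 11)) + 0.5) * 0x1.0p-53;
    }

    inline double norm() {
        if (has_cached) {
            has_cached = false;
            return cached_norm;
        }
        double u1 = unif(), u2 = unif();
        double r = std::sqrt(-2.0 * std::log(u1));
        double a = 6.283185307179586 * u2;
        cached_norm = r * std::sin(a);
        has_cached = true;
        return r * std::cos(a);
    }
};

}  // namespace

// Softmax probability of choosing option 1. tau = 0 is the greedy limit
// (argmax with a fair-coin tie-break handled by returning 0.5 at equality).
static inline double p_choose1(double x1, double x2, double tau) {
    if (tau <= 0.0) {
        if (x1 > x2) return 1.0;
        if (x1 < x2) return 0.0;
        return 0.5;
    }
    double d = (x1 - x2) / tau;
    if (d > 500.0) return 1.0;
    if (d < -500.0) return 0.0;
    return 1.0 / (1.0 + std::exp(-d));
}

// Simulate one session of the noisy Kalman-filter agent on a fixed schedule.
// All reward inputs are in points (1-99); the agent works on the 0-1 scale.
// reinit[t] == TRUE resets the learner's state before trial t.
// [[Rcpp::export]]
IntegerVector cpp_simulate_choices(NumericVector reward1, NumericVector reward2,
                                   LogicalVector reinit,
                                   double zeta, double delta, double tau,
                                   double vs, double vd, double v0) {
    int n = reward1.size();
    IntegerVector choice(n);
    double x1 = 0.5, x2 = 0.5, v1 = v0, v2 = v0;
    for (int t = 0; t < n; ++t) {
        if (reinit[t]) { x1 = 0.5; x2 = 0.5; v1 = v0; v2 = v0; }
        double p1 = p_choose1(x1, x2, tau);
        int c = (unif_rand() < p1) ? 1 : 2;
        choice[t] = c;
        double r = ((c == 1) ? reward1[t] : reward2[t]) / 100.0;
        if (c == 1) {
            double k = v1 / (v1 + vs);
            double up = k * (r - x1);
            double eta = zeta * std::fabs(up);
            x1 += up + ((eta > 0.0) ? norm_rand() * eta : 0.0);
            v1 = (1.0 - k) * v1 + vd;
            x2 += delta * (0.5 - x2);
            v2 += vd;
        } else {
            double k = v2 / (v2 + vs);
            double up = k * (r - x2);
            double eta = zeta * std::fabs(up);
            x2 += up + ((eta > 0.0) ? norm_rand() * eta : 0.0);
            v2 = (1.0 - k) * v2 + vd;
            x1 += delta * (0.5 - x1);
            v1 += vd;
        }
    }
    return choice;
}

// Accuracy of the greedy (optimal) Kalman filter over n_sims fresh runs of a
// schedule; rewards are resampled each run from per-trial beta distributions
// given by shape parameters (a1, b1, a2, b2), scaled to 1-99 and rounded.
// [[Rcpp::export]]
double cpp_accuracy_greedy(NumericVector mean1, NumericVector mean2,
                           LogicalVector reinit,
                           NumericVector a1, NumericVector b1,
                           NumericVector a2, NumericVector b2,
                           double vs, double vd, double v0, int n_sims) {
    int n = mean1.size();
    double n_correct = 0.0;
    for (int s = 0; s < n_sims; ++s) {
        double x1 = 0.5, x2 = 0.5, v1 = v0, v2 = v0;
        for (int t = 0; t < n; ++t) {
            if (reinit[t]) { x1 = 0.5; x2 = 0.5; v1 = v0; v2 = v0; }
            int c;
            if (x1 > x2) c = 1;
            else if (x2 > x1) c = 2;
            else c = (unif_rand() < 0.5) ? 1 : 2;
            int best = (mean1[t] > mean2[t]) ? 1 : 2;
            if (c == best) n_correct += 1.0;
            double draw = (c == 1) ? R::rbeta(a1[t], b1[t]) : R::rbeta(a2[t], b2[t]);
            double rpts = std::floor(1.0 + 98.0 * draw + 0.5);
            if (rpts < 1.0) rpts = 1.0;
            if (rpts > 99.0) rpts = 99.0;
            double r = rpts / 100.0;
            if (c == 1) {
                double k = v1 / (v1 + vs);
                x1 += k * (r - x1);
                v1 = (1.0 - k) * v1 + vd;
                v2 += vd;
            } else {
                double k = v2 / (v2 + vs);
                x2 += k * (r - x2);
                v2 = (1.0 - k) * v2 + vd;
                v1 += vd;
            }
        }
    }
    return n_correct / ((double)n_sims * (double)n);
}

// Bootstrap particle filter log-likelihood of an observed choice sequence
// under the noisy Kalman filter. Posterior variances are deterministic given
// the choices and tracked outside the particle set; only the value means
// (x1, x2) are latent. Weights use the softmax probability of the observed
// choice; systematic resampling when ESS < ess_frac * n_particles. When the
// per-trial marginal probability underflows (possible at tau = 0), it is
// floored at 1/(2 * n_particles).
// [[Rcpp::export]]
double cpp_pf_loglik(IntegerVector choice, NumericVector reward_chosen,
                     LogicalVector reinit,
                     double zeta, double delta, double tau,
                     double vs, double vd, double v0,
                     int n_particles, double ess_frac, double seed) {
    FastRng rng((uint64_t)seed);
    int n = choice.size();
    int N = n_particles;
    std::vector<double> x1(N), x2(N), W(N), g(N), nx1(N), nx2(N);
    double v1 = v0, v2 = v0;
    double ll = 0.0;
    double floor_p = 1.0 / (2.0 * (double)N);
    for (int t = 0; t < n; ++t) {
        if (reinit[t]) {
            std::fill(x1.begin(), x1.end(), 0.5);
            std::fill(x2.begin(), x2.end(), 0.5);
            std::fill(W.begin(), W.end(), 1.0 / (double)N);
            v1 = v0; v2 = v0;
        }
        int c = choice[t];
        double mg = 0.0;
        for (int i = 0; i < N; ++i) {
            double p1 = p_choose1(x1[i], x2[i], tau);
            g[i] = (c == 1) ? p1 : (1.0 - p1);
            mg += W[i] * g[i];
        }
        if (mg < floor_p) {
            ll += std::log(floor_p);
            std::fill(W.begin(), W.end(), 1.0 / (double)N);
        } else {
            ll += std::log(mg);
            double ess_inv = 0.0;
            for (int i = 0; i < N; ++i) {
                W[i] = W[i] * g[i] / mg;
                ess_inv += W[i] * W[i];
            }
            if (1.0 / ess_inv < ess_frac * (double)N) {
                // systematic resampling
                double u = rng.unif() / (double)N;
                double cum = W[0];
                int j = 0;
                for (int i = 0; i < N; ++i) {
                    double target = u + (double)i / (double)N;
                    while (cum < target && j < N - 1) { ++j; cum += W[j]; }
                    nx1[i] = x1[j];
                    nx2[i] = x2[j];
                }
                std::swap(x1, nx1);
                std::swap(x2, nx2);
                std::fill(W.begin(), W.end(), 1.0 / (double)N);
            }
        }
        // propagate through the observed choice and reward
        double r = reward_chosen[t];
        if (c == 1) {
            double k = v1 / (v1 + vs);
            for (int i = 0; i < N; ++i) {
                double up = k * (r - x1[i]);
                double eta = zeta * std::fabs(up);
                x1[i] += up + ((eta > 0.0) ? rng.norm() * eta : 0.0);
                x2[i] += delta * (0.5 - x2[i]);
            }
            v1 = (1.0 - k) * v1 + vd;
            v2 += vd;
        } else {
            double k = v2 / (v2 + vs);
            for (int i = 0; i < N; ++i) {
                double up = k * (r - x2[i]);
                double eta = zeta * std::fabs(up);
                x2[i] += up + ((eta > 0.0) ? rng.norm() * eta : 0.0);
                x1[i] += delta * (0.5 - x1[i]);
            }
            v2 = (1.0 - k) * v2 + vd;
            v1 += vd;
        }
    }
    return ll;
}

// Mean reward excess (obtained minus foregone, in points) of the noisy agent
// over n_sims traversals of a fixed schedule with realized rewards.
// [[Rcpp::export]]
double cpp_reward_excess(NumericVector reward1, NumericVector reward2,
                         LogicalVector reinit,
                         double zeta, double delta, double tau,
                         double vs, double vd, double v0, int n_sims) {
    int n = reward1.size();
    double total = 0.0;
    for (int s = 0; s < n_sims; ++s) {
        double x1 = 0.5, x2 = 0.5, v1 = v0, v2 = v0;
        for (int t = 0; t < n; ++t) {
            if (reinit[t]) { x1 = 0.5; x2 = 0.5; v1 = v0; v2 = v0; }
            double p1 = p_choose1(x1, x2, tau);
            int c = (unif_rand() < p1) ? 1 : 2;
            double obt = (c == 1) ? reward1[t] : reward2[t];
            double forg = (c == 1) ? reward2[t] : reward1[t];
            total += obt - forg;
            double r = obt / 100.0;
            if (c == 1) {
                double k = v1 / (v1 + vs);
                double up = k * (r - x1);
                double eta = zeta * std::fabs(up);
                x1 += up + ((eta > 0.0) ? norm_rand() * eta : 0.0);
                v1 = (1.0 - k) * v1 + vd;
                x2 += delta * (0.5 - x2);
                v2 += vd;
            } else {
                double k = v2 / (v2 + vs);
                double up = k * (r - x2);
                double eta = zeta * std::fabs(up);
                x2 += up + ((eta > 0.0) ? norm_rand() * eta : 0.0);
                v2 = (1.0 - k) * v2 + vd;
                x1 += delta * (0.5 - x1);
                v1 += vd;
            }
        }
    }
    return total / ((double)n_sims * (double)n);
}
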