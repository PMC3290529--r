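#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the full two-layer, multi-channel grid.
//
// Layer-1 neurons are driven by the stimulus schedule only (no inhibition).
// Layer-2 neurons read the layer-1 spike maps of the *previous* step (one-dt
// transmission delay): retinotopic excitation w_exc * S plus a spatially
// constant pooled term w_inh * sum(S) / N^2 per source channel.
//
// The u update uses the pre-update v (simultaneous Euler); the reset is
// checked on the updated v, applied before the next step, and the spike is
// recorded at the step where threshold was crossed.  After reset/update v is
// clipped from below at v_floor.
//
// Stimulus events carry signed weights.  At each step the drive of a channel
// is combined as: pixelwise max over active positive-weight events plus
// pixelwise min over active negative-weight events, which reduces to the
// binary OR of the frames times the weight when all weights are equal.
//
// [[Rcpp::export]]
List run_network_cpp(int N, int n_steps, double dt,
                     List params,      // a, b, c, d, v_peak, capacitance
                     double v0, double u0, double v_floor,
                     int n_channels,
                     List events,      // per event: channel, frame (N*N), on, off, weight
                     List wiring)      // per channel: exc_src, inh_src, w_exc, w_inh
{
    const double a  = as<double>(params["a"]);
    const double b  = as<double>(params["b"]);
    const double cr = as<double>(params["c"]);
    const double d  = as<double>(params["d"]);
    const double vp = as<double>(params["v_peak"]);
    const double cap = as<double>(params["capacitance"]);
    const int n2 = N * N;
    const int n_pop = 2 * n_channels;     // layer-1 channels then layer-2 channels

    // unpack events
    const int n_ev = events.size();
    std::vector<NumericVector> ev_frame(n_ev);
    std::vector<int> ev_ch(n_ev), ev_on(n_ev), ev_off(n_ev);
    std::vector<double> ev_w(n_ev);
    for (int e = 0; e < n_ev; ++e) {
        List ev = events[e];
        ev_ch[e] = as<int>(ev["channel"]) - 1;
        ev_frame[e] = as<NumericVector>(ev["frame"]);
        if (ev_frame[e].size() != n2) stop("event frame has wrong size");
        ev_on[e]  = as<int>(ev["on"]);
        ev_off[e] = as<int>(ev["off"]);
        ev_w[e]   = as<double>(ev["weight"]);
    }

    std::vector<IntegerVector> exc_src(n_channels), inh_src(n_channels);
    std::vector<double> w_exc(n_channels), w_inh(n_channels);
    for (int ch = 0; ch < n_channels; ++ch) {
        List w = wiring[ch];
        exc_src[ch] = as<IntegerVector>(w["exc_src"]);
        inh_src[ch] = as<IntegerVector>(w["inh_src"]);
        w_exc[ch] = as<double>(w["w_exc"]);
        w_inh[ch] = as<double>(w["w_inh"]);
    }

    // state
    std::vector< std::vector<double> > v(n_pop, std::vector<double>(n2, v0));
    std::vector< std::vector<double> > u(n_pop, std::vector<double>(n2, u0));
    // layer-1 spike maps of the previous step, one per channel
    std::vector< std::vector<double> > S_prev(n_channels, std::vector<double>(n2, 0.0));
    std::vector< std::vector<double> > S_curr(n_channels, std::vector<double>(n2, 0.0));
    std::vector<double> S_sum_prev(n_channels, 0.0), S_sum_curr(n_channels, 0.0);

    std::vector<int> out_step, out_pop, out_idx;
    std::vector<double> Ipos(n2), Ineg(n2), I(n2);

    for (int k = 0; k < n_steps; ++k) {
        for (int ch = 0; ch < n_channels; ++ch) {
            std::fill(S_curr[ch].begin(), S_curr[ch].end(), 0.0);
            S_sum_curr[ch] = 0.0;
        }
        for (int pop = 0; pop < n_pop; ++pop) {
            const int layer = pop < n_channels ? 0 : 1;
            const int ch = pop % n_channels;

            if (layer == 0) {
                std::fill(Ipos.begin(), Ipos.end(), 0.0);
                std::fill(Ineg.begin(), Ineg.end(), 0.0);
                for (int e = 0; e < n_ev; ++e) {
                    if (ev_ch[e] != ch || k < ev_on[e] || k >= ev_off[e]) continue;
                    const NumericVector& F = ev_frame[e];
                    const double w = ev_w[e];
                    if (w >= 0) {
                        for (int i = 0; i < n2; ++i) {
                            double x = w * F[i];
                            if (x > Ipos[i]) Ipos[i] = x;
                        }
                    } else {
                        for (int i = 0; i < n2; ++i) {
                            double x = w * F[i];
                            if (x < Ineg[i]) Ineg[i] = x;
                        }
                    }
                }
                for (int i = 0; i < n2; ++i) I[i] = Ipos[i] + Ineg[i];
            } else {
                std::fill(I.begin(), I.end(), 0.0);
                const IntegerVector& ex = exc_src[ch];
                for (int s = 0; s < ex.size(); ++s) {
                    const std::vector<double>& S = S_prev[ex[s] - 1];
                    for (int i = 0; i < n2; ++i) I[i] += w_exc[ch] * S[i];
                }
                const IntegerVector& in = inh_src[ch];
                double pooled = 0.0;
                for (int s = 0; s < in.size(); ++s)
                    pooled += w_inh[ch] * S_sum_prev[in[s] - 1] / (double)n2;
                if (pooled != 0.0)
                    for (int i = 0; i < n2; ++i) I[i] += pooled;
            }

            std::vector<double>& vv = v[pop];
            std::vector<double>& uu = u[pop];
            for (int i = 0; i < n2; ++i) {
                const double vi = vv[i];
                double vn = vi + dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - uu[i] + I[i] / cap);
                double un = uu[i] + dt * a * (b * vi - uu[i]);
                if (!std::isfinite(vn) || !std::isfinite(un))
                    stop("non-finite membrane state at step %d (channel %d, layer %d)",
                         k + 1, ch + 1, layer + 1);
                if (vn >= vp) {
                    vn = cr;
                    un += d;
                    out_step.push_back(k);
                    out_pop.push_back(pop);
                    out_idx.push_back(i);
                    if (layer == 0) {
                        S_curr[ch][i] = 1.0;
                        S_sum_curr[ch] += 1.0;
                    }
                }
                if (vn < v_floor) vn = v_floor;
                vv[i] = vn;
                uu[i] = un;
            }
        }
        for (int ch = 0; ch < n_channels; ++ch) {
            S_prev[ch].swap(S_curr[ch]);
            S_sum_prev[ch] = S_sum_curr[ch];
        }
    }

    return List::create(_["step"] = wrap(out_step),
                        _["pop"]  = wrap(out_pop),
                        _["idx"]  = wrap(out_idx));
}
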