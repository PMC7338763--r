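// Branch-site codon-model log-likelihood by Felsenstein pruning.
//
// The codon rate matrices arrive pre-built (61x61, uniform stationary
// distribution, mean rate 1) for the three omega values (omega0, 1,
// omega2); with uniform codon frequencies they are symmetric, so
// transition matrices come from a single symmetric eigendecomposition
// per omega. Site classes follow the standard branch-site ("model A")
// layout: (bg, fg) omega pairs (w0,w0), (1,1), (w0,w2), (1,w2) with
// proportions p0, p1, p2*p0/(p0+p1), p2*p1/(p0+p1).
//
// Classes (w0,w0) and (1,1) are plain prunings at a single omega; the
// two selection classes differ from them only on the foreground edges,
// so their conditionals are recomputed only along the paths from the
// foreground edges to the root.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat pmat(const arma::mat& U, const arma::vec& ev, double t) {
    arma::mat W = U;
    W.each_row() %= arma::exp(ev.t() * t);
    return W * U.t();
}

// [[Rcpp::export(name = ".bs_lnl_cpp")]]
double bs_lnl_cpp(const arma::imat& edge,      // nedge x 2, postorder, 1-based
                  const arma::vec& blen,       // per edge
                  const arma::ivec& fg,        // per edge, 0/1
                  int ntip, int nnode,
                  const arma::imat& tipstate,  // ntip x npat, 0-based codons
                  const arma::vec& weights,    // npat
                  const arma::mat& Q0, const arma::mat& Q1,
                  const arma::mat& Q2,
                  double p0, double p1) {
    const int S = 61;
    const int npat = tipstate.n_cols;
    const int nedge = edge.n_rows;
    const int nall = ntip + nnode;
    const int root = ntip;   // 0-based; ape root = ntip + 1 (1-based)

    arma::mat U0, U1, U2;
    arma::vec e0, e1, e2;
    arma::eig_sym(e0, U0, Q0);
    arma::eig_sym(e1, U1, Q1);
    const bool any_fg = arma::any(fg != 0);
    if (any_fg) arma::eig_sym(e2, U2, Q2);

    // transition matrices: P at the two background omegas for all edges,
    // at omega2 for foreground edges only
    std::vector<arma::mat> Pb[2];
    Pb[0].resize(nedge); Pb[1].resize(nedge);
    std::vector<arma::mat> Pfg(nedge);
    for (int e = 0; e < nedge; ++e) {
        Pb[0][e] = pmat(U0, e0, blen(e));
        Pb[1][e] = pmat(U1, e1, blen(e));
        if (fg(e)) Pfg[e] = pmat(U2, e2, blen(e));
    }

    // dirty nodes: ancestors (incl. parent) of any foreground edge
    std::vector<int> parent(nall, -1);
    for (int e = 0; e < nedge; ++e) parent[edge(e, 1) - 1] = edge(e, 0) - 1;
    std::vector<bool> dirty(nall, false);
    for (int e = 0; e < nedge; ++e) {
        if (!fg(e)) continue;
        for (int v = edge(e, 0) - 1; v >= 0; v = parent[v]) {
            if (dirty[v]) break;
            dirty[v] = true;
        }
    }

    arma::mat logsite(4, npat);

    auto tip_cond = [&](const arma::mat& P, int ch) {
        arma::mat cond(S, npat);
        for (int s = 0; s < npat; ++s) cond.col(s) = P.col(tipstate(ch, s));
        return cond;
    };

    for (int b = 0; b < 2; ++b) {
        // base pruning: all edges at background omega b
        std::vector<arma::mat> L(nall);
        std::vector<arma::rowvec> nscale(nall);
        std::vector<bool> seen(nall, false);
        std::vector<arma::mat> econd(nedge);
        std::vector<arma::rowvec> escale(nedge);
        for (int e = 0; e < nedge; ++e) {
            int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
            arma::rowvec chscale(npat, arma::fill::zeros);
            if (ch < ntip) econd[e] = tip_cond(Pb[b][e], ch);
            else { econd[e] = Pb[b][e] * L[ch]; chscale = nscale[ch]; }
            escale[e] = chscale;
            if (!seen[par]) {
                L[par] = econd[e]; nscale[par] = chscale; seen[par] = true;
            } else {
                L[par] %= econd[e]; nscale[par] += chscale;
            }
        }
        arma::rowvec mx = arma::max(L[root], 0);
        logsite.row(b) = arma::log(arma::sum(L[root].each_row() / mx, 0) /
                                   (double)S) +
            arma::log(mx) + nscale[root];

        if (!any_fg) continue;
        // derived class: foreground edges switch to omega2; recompute the
        // dirty path only
        std::vector<arma::mat> Ld(nall);
        std::vector<arma::rowvec> nsd(nall);
        std::vector<bool> seend(nall, false);
        for (int e = 0; e < nedge; ++e) {
            int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
            if (!dirty[par]) continue;
            bool ch_dirty = ch >= ntip && dirty[ch];
            arma::mat cond;
            arma::rowvec chscale(npat, arma::fill::zeros);
            if (fg(e)) {
                if (ch < ntip) cond = tip_cond(Pfg[e], ch);
                else if (ch_dirty) { cond = Pfg[e] * Ld[ch]; chscale = nsd[ch]; }
                else { cond = Pfg[e] * L[ch]; chscale = nscale[ch]; }
            } else if (ch_dirty) {
                cond = Pb[b][e] * Ld[ch]; chscale = nsd[ch];
            } else {
                cond = econd[e]; chscale = escale[e];  // clean: reuse
            }
            if (!seend[par]) {
                Ld[par] = cond; nsd[par] = chscale; seend[par] = true;
            } else {
                Ld[par] %= cond; nsd[par] += chscale;
            }
        }
        arma::rowvec mxd = arma::max(Ld[root], 0);
        logsite.row(2 + b) = arma::log(arma::sum(Ld[root].each_row() / mxd, 0) /
                                       (double)S) +
            arma::log(mxd) + nsd[root];
    }
    if (!any_fg) {
        logsite.row(2) = logsite.row(0);
        logsite.row(3) = logsite.row(1);
    }

    const double p2 = 1.0 - p0 - p1;
    const double denom = p0 + p1;
    double props[4] = { p0, p1, p2 * p0 / denom, p2 * p1 / denom };
    double lnl = 0.0;
    for (int s = 0; s < npat; ++s) {
        double m = logsite.col(s).max();
        double acc = 0.0;
        for (int c = 0; c < 4; ++c) acc += props[c] * std::exp(logsite(c, s) - m);
        lnl += weights(s) * (m + std::log(acc));
    }
    return lnl;
}
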