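#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline char complement_base(char b) {
    switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string &s) {
    std::string out(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i)
        out[s.size() - 1 - i] = complement_base(s[i]);
    return out;
}

// Merge paired reads by the best ungapped overlap.
// r2 is given in sequencing orientation and reverse-complemented here.
// Best overlap = lowest mismatch fraction; ties go to the longer overlap
// (overlaps are scanned in decreasing length). Disagreeing bases in the
// overlap resolve to the higher-Phred call (tie -> r1), quality = max.
// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector r1, CharacterVector q1,
                     CharacterVector r2, CharacterVector q2,
                     int min_overlap, double max_mismatch_frac) {
    int n = r1.size();
    CharacterVector merged(n), mqual(n), status(n);
    IntegerVector overlap_len(n), n_mismatch(n);

    for (int i = 0; i < n; ++i) {
        std::string s1 = as<std::string>(r1[i]);
        std::string qs1 = as<std::string>(q1[i]);
        std::string s2 = revcomp(as<std::string>(r2[i]));
        std::string qs2 = as<std::string>(q2[i]);
        std::reverse(qs2.begin(), qs2.end());
        int L1 = (int)s1.size(), L2 = (int)s2.size();

        if (std::min(L1, L2) < min_overlap) {
            merged[i] = NA_STRING; mqual[i] = NA_STRING;
            status[i] = "too_short";
            overlap_len[i] = NA_INTEGER; n_mismatch[i] = NA_INTEGER;
            continue;
        }

        int best_ov = -1, best_mm = 0;
        double best_frac = 1e9;
        for (int ov = std::min(L1, L2); ov >= min_overlap; --ov) {
            int allowed = (int)std::floor(max_mismatch_frac * ov + 1e-9);
            int mm = 0;
            bool ok = true;
            for (int k = 0; k < ov; ++k) {
                if (s1[L1 - ov + k] != s2[k]) {
                    if (++mm > allowed) { ok = false; break; }
                }
            }
            if (ok) {
                double frac = (double)mm / ov;
                if (frac < best_frac - 1e-12) {
                    best_frac = frac; best_ov = ov; best_mm = mm;
                }
            }
        }

        if (best_ov < 0) {
            merged[i] = NA_STRING; mqual[i] = NA_STRING;
            status[i] = "no_overlap";
            overlap_len[i] = NA_INTEGER; n_mismatch[i] = NA_INTEGER;
            continue;
        }

        int ov = best_ov;
        int Lm = L1 + L2 - ov;
        std::string ms; ms.reserve(Lm);
        std::string mq; mq.reserve(Lm);
        ms.append(s1, 0, L1 - ov);
        mq.append(qs1, 0, L1 - ov);
        for (int k = 0; k < ov; ++k) {
            char b1 = s1[L1 - ov + k], b2 = s2[k];
            char c1 = qs1[L1 - ov + k], c2 = qs2[k];
            char qmax = c1 >= c2 ? c1 : c2;
            if (b1 == b2) {
                ms.push_back(b1);
            } else if (c2 > c1) {
                ms.push_back(b2);
            } else {
                ms.push_back(b1);  // higher r1 quality, or tie -> r1
            }
            mq.push_back(qmax);
        }
        ms.append(s2, ov, L2 - ov);
        mq.append(qs2, ov, L2 - ov);

        merged[i] = ms; mqual[i] = mq;
        status[i] = "merged";
        overlap_len[i] = ov; n_mismatch[i] = best_mm;
    }
    return List::create(_["sequence"] = merged, _["qualities"] = mqual,
                        _["status"] = status, _["overlap"] = overlap_len,
                        _["mismatches"] = n_mismatch);
}

// Assign merged reads to bisulfite-converted amplicon references.
// conv_refs: reference with every non-CpG C converted to T;
// cpg_masks: TRUE at the C of each CpG (C or T both count as a match there).
// A read is compared in both orientations at every ungapped offset with
// full containment of the shorter sequence and aligned length >= min_len;
// score = mismatch fraction over the aligned length. The read is assigned
// to the unique gene with minimal score <= max_mismatch_frac; ties between
// genes or no qualifying gene leave it unassigned.
// [[Rcpp::export(name = ".assign_reads_cpp")]]
List assign_reads_cpp(CharacterVector reads, List conv_refs, List cpg_masks,
                      double max_mismatch_frac, int min_len) {
    int n = reads.size();
    int ng = conv_refs.size();
    std::vector<std::string> refs(ng);
    std::vector<std::vector<int> > cpg(ng);
    for (int g = 0; g < ng; ++g) {
        refs[g] = as<std::string>(conv_refs[g]);
        LogicalVector m = cpg_masks[g];
        cpg[g].assign(m.begin(), m.end());
    }

    IntegerVector gene(n), ref_start(n), read_start(n), aln_len(n);
    NumericVector score(n);
    CharacterVector strand(n), oriented(n), reason(n);

    for (int i = 0; i < n; ++i) {
        if (reads[i] == NA_STRING) {
            gene[i] = NA_INTEGER; score[i] = NA_REAL;
            ref_start[i] = NA_INTEGER; read_start[i] = NA_INTEGER;
            aln_len[i] = NA_INTEGER;
            strand[i] = NA_STRING; oriented[i] = NA_STRING;
            reason[i] = "missing";
            continue;
        }
        std::string fwd = as<std::string>(reads[i]);
        int Lq = (int)fwd.size();
        if (Lq < min_len) {
            gene[i] = NA_INTEGER; score[i] = NA_REAL;
            ref_start[i] = NA_INTEGER; read_start[i] = NA_INTEGER;
            aln_len[i] = NA_INTEGER;
            strand[i] = NA_STRING; oriented[i] = NA_STRING;
            reason[i] = "too_short";
            continue;
        }
        std::string rev = revcomp(fwd);

        double best_frac = 1e9;
        int best_gene = -1, best_refs = 0, best_reads = 0, best_aln = 0;
        int best_strand = 0;  // 0 = '+', 1 = '-'
        bool tie = false;

        for (int st = 0; st < 2; ++st) {
            const std::string &q = st == 0 ? fwd : rev;
            for (int g = 0; g < ng; ++g) {
                const std::string &ref = refs[g];
                const std::vector<int> &msk = cpg[g];
                int Lr = (int)ref.size();
                int alen = std::min(Lq, Lr);
                if (alen < min_len) continue;
                int noff = std::abs(Lq - Lr) + 1;
                for (int o = 0; o < noff; ++o) {
                    // rs/qs: start of aligned block in ref / read
                    int rs = Lq <= Lr ? o : 0;
                    int qs = Lq <= Lr ? 0 : o;
                    double lim = std::min(max_mismatch_frac,
                                          best_frac + 1e-12);
                    int allowed = (int)std::floor(lim * alen + 1e-9);
                    int mm = 0;
                    bool ok = true;
                    for (int k = 0; k < alen; ++k) {
                        char b = q[qs + k];
                        char p = ref[rs + k];
                        bool match = msk[rs + k] ? (b == 'C' || b == 'T')
                                                 : (b == p);
                        if (!match && ++mm > allowed) { ok = false; break; }
                    }
                    if (!ok) continue;
                    double frac = (double)mm / alen;
                    if (frac < best_frac - 1e-12) {
                        best_frac = frac; best_gene = g;
                        best_refs = rs; best_reads = qs;
                        best_aln = alen; best_strand = st;
                        tie = false;
                    } else if (frac < best_frac + 1e-12 && g != best_gene) {
                        tie = true;
                    }
                }
            }
        }

        if (best_gene < 0 || best_frac > max_mismatch_frac + 1e-12) {
            gene[i] = NA_INTEGER; score[i] = NA_REAL;
            ref_start[i] = NA_INTEGER; read_start[i] = NA_INTEGER;
            aln_len[i] = NA_INTEGER;
            strand[i] = NA_STRING; oriented[i] = NA_STRING;
            reason[i] = "no_match";
        } else if (tie) {
            gene[i] = NA_INTEGER; score[i] = best_frac;
            ref_start[i] = NA_INTEGER; read_start[i] = NA_INTEGER;
            aln_len[i] = NA_INTEGER;
            strand[i] = NA_STRING; oriented[i] = NA_STRING;
            reason[i] = "ambiguous";
        } else {
            gene[i] = best_gene + 1;
            score[i] = best_frac;
            ref_start[i] = best_refs + 1;   // 1-based
            read_start[i] = best_reads + 1; // 1-based, in oriented read
            aln_len[i] = best_aln;
            strand[i] = best_strand == 0 ? "+" : "-";
            oriented[i] = best_strand == 0 ? fwd : rev;
            reason[i] = "assigned";
        }
    }
    return List::create(_["gene"] = gene, _["score"] = score,
                        _["ref_start"] = ref_start,
                        _["read_start"] = read_start,
                        _["aln_len"] = aln_len,
                        _["strand"] = strand, _["oriented"] = oriented,
                        _["reason"] = reason);
}
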