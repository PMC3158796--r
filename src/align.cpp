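// Seed-and-extend nucleotide local alignment with BLAST-tabular output
// semantics: exact k-mer seeding on both strands, ungapped X-drop extension,
// Karlin-Altschul bit scores. One best HSP per (query, subject) pair by
// default; minus-strand hits are encoded by sstart > send.

#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // N or anything else: never matches
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': case 'a': r[i] = 'T'; break;
      case 'C': case 'c': r[i] = 'G'; break;
      case 'G': case 'g': r[i] = 'C'; break;
      case 'T': case 't': r[i] = 'A'; break;
      default: r[i] = 'N';
    }
  }
  return r;
}

struct Hsp {
  int sidx;
  int strand;      // 0 forward, 1 reverse
  int qs, qe;      // 0-based inclusive, on the strand-adjusted query
  int ss, se;      // 0-based inclusive on subject (always ascending)
  int matches;
  int score;       // raw score
};

// Extend a seed (length k exact match) on one diagonal, ungapped, X-drop.
static Hsp extend_seed(const std::vector<int> &q, const std::vector<int> &s,
                       int qpos, int spos, int k,
                       int match, int mismatch, int xdrop) {
  const int qn = (int)q.size(), sn = (int)s.size();
  int score = k * match;
  // right extension
  int best = score, best_qe = qpos + k - 1;
  int i = qpos + k, j = spos + k, cur = score;
  while (i < qn && j < sn) {
    cur += (q[i] < 4 && q[i] == s[j]) ? match : mismatch;
    if (cur > best) { best = cur; best_qe = i; }
    if (cur < best - xdrop) break;
    ++i; ++j;
  }
  // left extension
  int best2 = best, best_qs = qpos;
  i = qpos - 1; j = spos - 1; cur = best;
  while (i >= 0 && j >= 0) {
    cur += (q[i] < 4 && q[i] == s[j]) ? match : mismatch;
    if (cur > best2) { best2 = cur; best_qs = i; }
    if (cur < best2 - xdrop) break;
    --i; --j;
  }
  Hsp h;
  h.qs = best_qs; h.qe = best_qe;
  h.ss = spos + (best_qs - qpos); h.se = spos + (best_qe - qpos);
  h.score = best2;
  int m = 0;
  for (int t = best_qs; t <= best_qe; ++t) {
    int u = t - qpos + spos;
    if (q[t] < 4 && q[t] == s[u]) ++m;
  }
  h.matches = m;
  return h;
}

// [[Rcpp::export(name = ".align_sets")]]
DataFrame align_sets_cpp(CharacterVector queries, CharacterVector subjects,
                         int k, int match, int mismatch, double xdrop,
                         double lambda, double K, double max_evalue,
                         bool best_per_pair) {
  const int nq = queries.size(), ns = subjects.size();
  CharacterVector qnames = queries.names();
  CharacterVector snames = subjects.names();

  // encode subjects and build the shared k-mer index
  std::vector<std::vector<int>> senc(ns);
  double n_total = 0.0;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  for (int si = 0; si < ns; ++si) {
    std::string s = as<std::string>(subjects[si]);
    n_total += (double)s.size();
    std::vector<int> enc(s.size());
    for (size_t i = 0; i < s.size(); ++i) enc[i] = base_code(s[i]);
    senc[si] = enc;
    if ((int)s.size() < k) continue;
    uint64_t km = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      if (enc[i] > 3) { run = 0; km = 0; continue; }
      km = ((km << 2) | (uint64_t)enc[i]) & mask;
      if (++run >= k) index[km].push_back({si, (int)i - k + 1});
    }
  }

  std::vector<std::string> out_q, out_s;
  std::vector<double> out_pid, out_ev, out_bit;
  std::vector<int> out_len, out_mm, out_gap, out_qs, out_qe, out_ss, out_se;

  const double ln2 = std::log(2.0);
  for (int qi = 0; qi < nq; ++qi) {
    std::string qf = as<std::string>(queries[qi]);
    const int Lq = (int)qf.size();
    // best HSP per subject for this query (if best_per_pair)
    std::map<int, std::pair<Hsp, int>> best; // sidx -> (hsp, strand)
    std::vector<std::pair<Hsp, int>> all;    // (hsp, strand)
    for (int strand = 0; strand < 2; ++strand) {
      std::string qs_str = (strand == 0) ? qf : revcomp(qf);
      std::vector<int> qenc(qs_str.size());
      for (size_t i = 0; i < qs_str.size(); ++i) qenc[i] = base_code(qs_str[i]);
      if (Lq < k) continue;
      // seeds grouped by (subject, diagonal)
      std::map<std::pair<int, long long>, std::vector<int>> diag_seeds;
      uint64_t km = 0; int run = 0;
      for (int i = 0; i < Lq; ++i) {
        if (qenc[i] > 3) { run = 0; km = 0; continue; }
        km = ((km << 2) | (uint64_t)qenc[i]) & mask;
        if (++run < k) continue;
        auto it = index.find(km);
        if (it == index.end()) continue;
        int qpos = i - k + 1;
        for (auto &hit : it->second) {
          long long diag = (long long)hit.second - qpos;
          diag_seeds[{hit.first, diag}].push_back(qpos);
        }
      }
      for (auto &ds : diag_seeds) {
        int sidx = ds.first.first;
        long long diag = ds.first.second;
        int covered_to = -1; // last query pos covered by an extension
        for (int qpos : ds.second) { // qpos ascending by construction
          if (qpos <= covered_to) continue;
          Hsp h = extend_seed(qenc, senc[sidx], qpos, (int)(qpos + diag), k,
                              match, mismatch, (int)xdrop);
          h.sidx = sidx; h.strand = strand;
          covered_to = h.qe;
          if (best_per_pair) {
            auto it = best.find(sidx);
            if (it == best.end() || h.score > it->second.first.score ||
                (h.score == it->second.first.score &&
                 (strand < it->second.second ||
                  (strand == it->second.second && h.qs < it->second.first.qs)))) {
              best[sidx] = {h, strand};
            }
          } else {
            all.push_back({h, strand});
          }
        }
      }
    }
    std::vector<std::pair<Hsp, int>> report;
    if (best_per_pair) {
      for (auto &b : best) report.push_back(b.second);
    } else {
      report = all;
    }
    for (auto &r : report) {
      const Hsp &h = r.first;
      int alen = h.qe - h.qs + 1;
      double bit = (lambda * h.score - std::log(K)) / ln2;
      double ev = (double)Lq * n_total * std::pow(2.0, -bit);
      if (ev > max_evalue) continue;
      int qstart, qend, sstart, send;
      if (r.second == 0) {
        qstart = h.qs + 1; qend = h.qe + 1;
        sstart = h.ss + 1; send = h.se + 1;
      } else {
        qstart = Lq - h.qe; qend = Lq - h.qs;
        sstart = h.se + 1; send = h.ss + 1; // sstart > send flags minus strand
      }
      out_q.push_back(as<std::string>(qnames[qi]));
      out_s.push_back(as<std::string>(snames[h.sidx]));
      out_pid.push_back(100.0 * (double)h.matches / (double)alen);
      out_len.push_back(alen);
      out_mm.push_back(alen - h.matches);
      out_gap.push_back(0);
      out_qs.push_back(qstart); out_qe.push_back(qend);
      out_ss.push_back(sstart); out_se.push_back(send);
      out_ev.push_back(ev); out_bit.push_back(bit);
    }
  }

  return DataFrame::create(
    _["qseqid"] = out_q, _["sseqid"] = out_s, _["pident"] = out_pid,
    _["length"] = out_len, _["mismatch"] = out_mm, _["gapopen"] = out_gap,
    _["qstart"] = out_qs, _["qend"] = out_qe, _["sstart"] = out_ss,
    _["send"] = out_se, _["evalue"] = out_ev, _["bitscore"] = out_bit,
    _["stringsAsFactors"] = false);
}
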