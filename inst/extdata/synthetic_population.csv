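sex,age_band,year,population
male,25-34,1986,580000
male,25-34,1987,580417
male,25-34,1988,580833
male,25-34,1989,581250
male,25-34,1990,581667
male,25-34,1991,582083
male,25-34,1992,582500
male,25-34,1993,582917
male,25-34,1994,583333
male,25-34,1995,583750
male,25-34,1996,584167
male,25-34,1997,584583
male,25-34,1998,585000
male,25-34,1999,585417
male,25-34,2000,585833
male,25-34,2001,586250
male,25-34,2002,586667
male,25-34,2003,587083
male,25-34,2004,587500
male,25-34,2005,587917
male,25-34,2006,588333
male,25-34,2007,588750
male,25-34,2008,589167
male,25-34,2009,589583
male,25-34,2010,590000
male,25-34,2025,700000
male,35-44,1986,600000
male,35-44,1987,601667
male,35-44,1988,603333
male,35-44,1989,605000
male,35-44,1990,606667
male,35-44,1991,608333
male,35-44,1992,610000
male,35-44,1993,611667
male,35-44,1994,613333
male,35-44,1995,615000
male,35-44,1996,616667
male,35-44,1997,618333
male,35-44,1998,620000
male,35-44,1999,621667
male,35-44,2000,623333
male,35-44,2001,625000
male,35-44,2002,626667
male,35-44,2003,628333
male,35-44,2004,630000
male,35-44,2005,631667
male,35-44,2006,633333
male,35-44,2007,635000
male,35-44,2008,636667
male,35-44,2009,638333
male,35-44,2010,640000
male,35-44,2025,640000
male,45-54,1986,500000
male,45-54,1987,505000
male,45-54,1988,510000
male,45-54,1989,515000
male,45-54,1990,520000
male,45-54,1991,525000
male,45-54,1992,530000
male,45-54,1993,535000
male,45-54,1994,540000
male,45-54,1995,545000
male,45-54,1996,550000
male,45-54,1997,555000
male,45-54,1998,560000
male,45-54,1999,565000
male,45-54,2000,570000
male,45-54,2001,575000
male,45-54,2002,580000
male,45-54,2003,585000
male,45-54,2004,590000
male,45-54,2005,595000
male,45-54,2006,600000
male,45-54,2007,605000
male,45-54,2008,610000
male,45-54,2009,615000
male,45-54,2010,620000
male,45-54,2025,650000
male,55-64,1986,430000
male,55-64,1987,436667
male,55-64,1988,443333
male,55-64,1989,450000
male,55-64,1990,456667
male,55-64,1991,463333
male,55-64,1992,470000
male,55-64,1993,476667
male,55-64,1994,483333
male,55-64,1995,490000
male,55-64,1996,496667
male,55-64,1997,503333
male,55-64,1998,510000
male,55-64,1999,516667
male,55-64,2000,523333
male,55-64,2001,530000
male,55-64,2002,536667
male,55-64,2003,543333
male,55-64,2004,550000
male,55-64,2005,556667
male,55-64,2006,563333
male,55-64,2007,570000
male,55-64,2008,576667
male,55-64,2009,583333
male,55-64,2010,590000
male,55-64,2025,590000
male,65-74,1986,380000
male,65-74,1987,382083
male,65-74,1988,384167
male,65-74,1989,386250
male,65-74,1990,388333
male,65-74,1991,390417
male,65-74,1992,392500
male,65-74,1993,394583
male,65-74,1994,396667
male,65-74,1995,398750
male,65-74,1996,400833
male,65-74,1997,402917
male,65-74,1998,405000
male,65-74,1999,407083
male,65-74,2000,409167
male,65-74,2001,411250
male,65-74,2002,413333
male,65-74,2003,415417
male,65-74,2004,417500
male,65-74,2005,419583
male,65-74,2006,421667
male,65-74,2007,423750
male,65-74,2008,425833
male,65-74,2009,427917
male,65-74,2010,430000
male,65-74,2025,560000
male,75-84,1986,180000
male,75-84,1987,182083
male,75-84,1988,184167
male,75-84,1989,186250
male,75-84,1990,188333
male,75-84,1991,190417
male,75-84,1992,192500
male,75-84,1993,194583
male,75-84,1994,196667
male,75-84,1995,198750
male,75-84,1996,200833
male,75-84,1997,202917
male,75-84,1998,205000
male,75-84,1999,207083
male,75-84,2000,209167
male,75-84,2001,211250
male,75-84,2002,213333
male,75-84,2003,215417
male,75-84,2004,217500
male,75-84,2005,219583
male,75-84,2006,221667
male,75-84,2007,223750
male,75-84,2008,225833
male,75-84,2009,227917
male,75-84,2010,230000
male,75-84,2025,400000
female,25-34,1986,560000
female,25-34,1987,560417
female,25-34,1988,560833
female,25-34,1989,561250
female,25-34,1990,561667
female,25-34,1991,562083
female,25-34,1992,562500
female,25-34,1993,562917
female,25-34,1994,563333
female,25-34,1995,563750
female,25-34,1996,564167
female,25-34,1997,564583
female,25-34,1998,565000
female,25-34,1999,565417
female,25-34,2000,565833
female,25-34,2001,566250
female,25-34,2002,566667
female,25-34,2003,567083
female,25-34,2004,567500
female,25-34,2005,567917
female,25-34,2006,568333
female,25-34,2007,568750
female,25-34,2008,569167
female,25-34,2009,569583
female,25-34,2010,570000
female,25-34,2025,670000
female,35-44,1986,580000
female,35-44,1987,581667
female,35-44,1988,583333
female,35-44,1989,585000
female,35-44,1990,586667
female,35-44,1991,588333
female,35-44,1992,590000
female,35-44,1993,591667
female,35-44,1994,593333
female,35-44,1995,595000
female,35-44,1996,596667
female,35-44,1997,598333
female,35-44,1998,600000
female,35-44,1999,601667
female,35-44,2000,603333
female,35-44,2001,605000
female,35-44,2002,606667
female,35-44,2003,608333
female,35-44,2004,610000
female,35-44,2005,611667
female,35-44,2006,613333
female,35-44,2007,615000
female,35-44,2008,616667
female,35-44,2009,618333
female,35-44,2010,620000
female,35-44,2025,610000
female,45-54,1986,490000
female,45-54,1987,495000
female,45-54,1988,500000
female,45-54,1989,505000
female,45-54,1990,510000
female,45-54,1991,515000
female,45-54,1992,520000
female,45-54,1993,525000
female,45-54,1994,530000
female,45-54,1995,535000
female,45-54,1996,540000
female,45-54,1997,545000
female,45-54,1998,550000
female,45-54,1999,555000
female,45-54,2000,560000
female,45-54,2001,565000
female,45-54,2002,570000
female,45-54,2003,575000
female,45-54,2004,580000
female,45-54,2005,585000
female,45-54,2006,590000
female,45-54,2007,595000
female,45-54,2008,600000
female,45-54,2009,605000
female,45-54,2010,610000
female,45-54,2025,630000
female,55-64,1986,440000
female,55-64,1987,446667
female,55-64,1988,453333
female,55-64,1989,460000
female,55-64,1990,466667
female,55-64,1991,473333
female,55-64,1992,480000
female,55-64,1993,486667
female,55-64,1994,493333
female,55-64,1995,500000
female,55-64,1996,506667
female,55-64,1997,513333
female,55-64,1998,520000
female,55-64,1999,526667
female,55-64,2000,533333
female,55-64,2001,540000
female,55-64,2002,546667
female,55-64,2003,553333
female,55-64,2004,560000
female,55-64,2005,566667
female,55-64,2006,573333
female,55-64,2007,580000
female,55-64,2008,586667
female,55-64,2009,593333
female,55-64,2010,600000
female,55-64,2025,590000
female,65-74,1986,420000
female,65-74,1987,421667
female,65-74,1988,423333
female,65-74,1989,425000
female,65-74,1990,426667
female,65-74,1991,428333
female,65-74,1992,430000
female,65-74,1993,431667
female,65-74,1994,433333
female,65-74,1995,435000
female,65-74,1996,436667
female,65-74,1997,438333
female,65-74,1998,440000
female,65-74,1999,441667
female,65-74,2000,443333
female,65-74,2001,445000
female,65-74,2002,446667
female,65-74,2003,448333
female,65-74,2004,450000
female,65-74,2005,451667
female,65-74,2006,453333
female,65-74,2007,455000
female,65-74,2008,456667
female,65-74,2009,458333
female,65-74,2010,460000
female,65-74,2025,580000
female,75-84,1986,260000
female,75-84,1987,262500
female,75-84,1988,265000
female,75-84,1989,267500
female,75-84,1990,270000
female,75-84,1991,272500
female,75-84,1992,275000
female,75-84,1993,277500
female,75-84,1994,280000
female,75-84,1995,282500
female,75-84,1996,285000
female,75-84,1997,287500
female,75-84,1998,290000
female,75-84,1999,292500
female,75-84,2000,295000
female,75-84,2001,297500
female,75-84,2002,300000
female,75-84,2003,302500
female,75-84,2004,305000
female,75-84,2005,307500
female,75-84,2006,310000
female,75-84,2007,312500
female,75-84,2008,315000
female,75-84,2009,317500
female,75-84,2010,320000
female,75-84,2025,460000
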